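# Shared fixture builders (all data generated in code; no files).

two_group_factor <- function(n_per_group = 4L) {
  factor(rep(c("control", "mutant"), each = n_per_group),
         levels = c("control", "mutant"))
}

# plain two-group gaussian matrix with optional per-feature effects
make_matrix <- function(n_features = 100L, n_per_group = 4L, effect = NULL,
                        noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_group
  x <- matrix(stats::rnorm(n_features * n, 20, noise_sd), n_features, n)
  if (!is.null(effect)) {
    x[, seq_len(n_per_group) + n_per_group] <-
      x[, seq_len(n_per_group) + n_per_group] + effect
  }
  rownames(x) <- sprintf("f%04d", seq_len(n_features))
  colnames(x) <- sprintf("S%02d", seq_len(n))
  x
}

# brute-force BH step-up, independent of stats::p.adjust
bh_brute <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(q)
  ord <- order(p[ok])
  adj <- p[ok][ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[ok[ord]] <- pmin(adj, 1)
  q
}

# brute-force TOM by triple loop
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# module-recovery study conditions: 3 strong latent-factor modules, the
# first coupled to the trait, in a 2000-protein 4v4 proteome
module_recovery_config <- function(seed) {
  sim_config(n_proteins = 2000L, n_phosphosites = 100L, n_modules = 3L,
             module_sizes = c(200L, 150L, 100L), latent_strength = 2,
             trait_coupling = 3, frac_de = 0, noise_sd = 0.5, seed = seed)
}

# kinase-inference study conditions: two shifted kinases among five,
# 30 true substrates each over 1000 sites
kinase_recovery_config <- function(seed) {
  sim_config(seed = seed)
}

run_kinase_inference <- function(study, seed) {
  g <- two_group_factor(study$config$n_per_group)
  norm <- normalize_site_by_protein(study$phospho$matrix,
                                    study$proteome$matrix,
                                    study$phospho$site_table, g)
  scores <- suppressMessages(kinase_substrate_score(
    norm$diff_matrix, study$phospho$site_table, study$kinase_models,
    study$phospho$annotation, seed = seed
  ))
  list(norm = norm, scores = scores)
}
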