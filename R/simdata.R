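#' Configuration for the synthetic proteome/phosphoproteome generator
#'
#' Bundles every knob of the simulator in one validated object. The defaults
#' describe the study design the pipeline targets: a small two-group DIA-style
#' experiment (control vs mutant, a few replicates each) in which a minority
#' of proteins are truly differential, phosphosites track their parent protein
#' plus kinase-driven shifts, and a handful of latent factors induce
#' block-correlated co-expression modules.
#'
#' @param n_per_group replicates per group (>= 2).
#' @param n_proteins number of proteins.
#' @param n_phosphosites number of phosphosites.
#' @param n_kinases number of simulated kinases (>= 1).
#' @param frac_de fraction of proteins that are truly differential.
#' @param effect_log2fc absolute log2 fold change of differential proteins.
#' @param noise_sd residual SD of protein log2 intensities.
#' @param site_noise_sd site-level residual SD added on top of the parent
#'   protein signal; defaults to `noise_sd / 2`.
#' @param kinase_shift numeric vector (length `n_kinases`, recycled) of
#'   per-kinase activity shifts for mutant samples, in units of `noise_sd`.
#'   Positive = substrates more phosphorylated in the mutant group.
#' @param n_substrates_per_kinase true substrates per kinase.
#' @param n_annotated_per_kinase "known" (annotated) substrates per kinase,
#'   drawn from the true substrates; feeds the kinase-substrate annotation
#'   table used as positive labels.
#' @param substrate_window_from_motif probability that a true substrate's
#'   sequence window is sampled from its kinase's PSSM (else background).
#' @param motif_sharpness in \[0, 1): 0 gives uniform (maximum-entropy)
#'   motif positions; values near 1 concentrate each informative position on
#'   a single preferred residue.
#' @param n_motif_positions informative (non-center) motif positions per
#'   kinase PSSM.
#' @param n_modules number of latent-factor co-expression modules (0 = none).
#' @param module_sizes integer vector of module sizes; default splits
#'   `round(0.075 * n_proteins)` per module.
#' @param latent_strength scale of per-protein loadings on the module latent
#'   factors (loading ~ latent_strength * U(0.5, 1)).
#' @param trait_coupling group separation of module 1's latent factor, in
#'   factor-SD units (0 = factors independent of the trait).
#' @param missing_rate fraction of intensities set missing.
#' @param missing_mechanism `"mcar"` (completely at random) or `"censor"`
#'   (left-censored: low intensities preferentially missing).
#' @param batch_effect_sd SD of additive per-batch offsets (0 = single batch).
#' @param seed integer seed; identical configs reproduce identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_group = 4L,
                       n_proteins = 2000L,
                       n_phosphosites = 1000L,
                       n_kinases = 5L,
                       frac_de = 0.1,
                       effect_log2fc = 2,
                       noise_sd = 0.5,
                       site_noise_sd = NULL,
                       kinase_shift = c(-1, 1, 0, 0, 0),
                       n_substrates_per_kinase = 30L,
                       n_annotated_per_kinase = 10L,
                       substrate_window_from_motif = 1,
                       motif_sharpness = 0.9,
                       n_motif_positions = 4L,
                       n_modules = 3L,
                       module_sizes = NULL,
                       latent_strength = 1,
                       trait_coupling = 0,
                       missing_rate = 0,
                       missing_mechanism = c("mcar", "censor"),
                       batch_effect_sd = 0,
                       seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  for (fr in c(frac_de, missing_rate, substrate_window_from_motif)) {
    if (fr < 0 || fr > 1) stop("fractions must lie in [0, 1]")
  }
  if (motif_sharpness < 0 || motif_sharpness >= 1) {
    stop("motif_sharpness must lie in [0, 1)")
  }
  if (n_modules > 0L) {
    if (is.null(module_sizes)) {
      module_sizes <- rep(max(10L, round(0.075 * n_proteins)), n_modules)
    }
    if (length(module_sizes) != n_modules) {
      stop("module_sizes must have length n_modules")
    }
    if (sum(module_sizes) > n_proteins) {
      stop("module_sizes must sum to at most n_proteins")
    }
  } else {
    module_sizes <- integer(0)
  }
  if (is.null(site_noise_sd)) site_noise_sd <- noise_sd / 2
  kinase_shift <- rep_len(as.numeric(kinase_shift), max(n_kinases, 1L))
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_proteins = as.integer(n_proteins),
    n_phosphosites = as.integer(n_phosphosites),
    n_kinases = as.integer(n_kinases),
    frac_de = frac_de,
    effect_log2fc = effect_log2fc,
    noise_sd = noise_sd,
    site_noise_sd = site_noise_sd,
    kinase_shift = kinase_shift,
    n_substrates_per_kinase = as.integer(n_substrates_per_kinase),
    n_annotated_per_kinase = as.integer(n_annotated_per_kinase),
    substrate_window_from_motif = substrate_window_from_motif,
    motif_sharpness = motif_sharpness,
    n_motif_positions = as.integer(n_motif_positions),
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    latent_strength = latent_strength,
    trait_coupling = trait_coupling,
    missing_rate = missing_rate,
    missing_mechanism = missing_mechanism,
    batch_effect_sd = batch_effect_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate kinase recognition motifs (PSSMs)
#'
#' Each kinase gets a 15-position x 20-residue position-specific scoring
#' matrix. The phospho-acceptor center position carries all its mass on S/T;
#' a random subset of flanking positions are informative, mixing a preferred
#' residue (weight `motif_sharpness`) with the uniform background; remaining
#' positions are uniform. Every row (position) sums to one.
#'
#' @param config a [sim_config()].
#' @return named list of 15 x 20 PSSM matrices (rows = window positions,
#'   columns = residues), names `K1`, `K2`, ...
#' @export
simulate_kinase_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_kinases < 1L) stop("n_kinases must be >= 1")
  set.seed(.stage_seed(config$seed, 1L))
  lapply(stats::setNames(seq_len(config$n_kinases),
                         paste0("K", seq_len(config$n_kinases))),
         function(k) {
    pssm <- matrix(1 / 20, nrow = WINDOW_WIDTH, ncol = 20,
                   dimnames = list(paste0("pos", seq_len(WINDOW_WIDTH)),
                                   AA_ALPHABET))
    flank <- setdiff(seq_len(WINDOW_WIDTH), WINDOW_CENTER)
    info <- sample(flank, min(config$n_motif_positions, length(flank)))
    pref <- sample(AA_ALPHABET, length(info), replace = TRUE)
    for (i in seq_along(info)) {
      row <- rep((1 - config$motif_sharpness) / 20, 20)
      row[match(pref[i], AA_ALPHABET)] <-
        row[match(pref[i], AA_ALPHABET)] + config$motif_sharpness
      pssm[info[i], ] <- row
    }
    center <- rep(0, 20)
    center[match(c("S", "T"), AA_ALPHABET)] <- c(0.7, 0.3)
    pssm[WINDOW_CENTER, ] <- center
    pssm
  })
}

#' Simulate a two-group proteome with known ground truth
#'
#' Log2 intensities are built additively: per-protein baseline, latent-factor
#' module contribution, group effect for truly differential proteins, batch
#' offset, and Gaussian noise; missing values are then inserted. Truly
#' differential proteins (fixed effect, random sign) are drawn from outside
#' the modules; with `trait_coupling > 0` module 1's latent factor separates
#' between groups, making that module coordinately trait-responsive (each
#' member's induced fold change is its loading times the coupling).
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (proteins x samples, log2 scale, `NA` missing),
#'   `metadata` (sample, group, trait, batch) and `truth` (de_labels,
#'   module_labels, latent_factors, loadings, batch_offsets).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, 2L))
  n <- 2L * config$n_per_group
  p <- config$n_proteins
  group <- rep(c("control", "mutant"), each = config$n_per_group)
  trait <- as.integer(group == "mutant")
  batch <- if (config$batch_effect_sd > 0) {
    rep_len(c(1L, 2L), n)  # interleaved so batch is not confounded with group
  } else {
    rep(1L, n)
  }
  metadata <- data.frame(
    sample = sprintf("S%02d", seq_len(n)),
    group = group, trait = trait, batch = batch,
    stringsAsFactors = FALSE
  )

  protein_id <- sprintf("P%04d", seq_len(p))
  baseline <- stats::rnorm(p, mean = 20, sd = 2)

  module_labels <- integer(p)
  loadings <- numeric(p)
  if (config$n_modules > 0L) {
    idx <- 1L
    for (m in seq_len(config$n_modules)) {
      members <- seq.int(idx, idx + config$module_sizes[m] - 1L)
      module_labels[members] <- m
      idx <- idx + config$module_sizes[m]
    }
    loadings[module_labels > 0L] <-
      config$latent_strength * stats::runif(sum(module_labels > 0L), 0.5, 1)
  }
  latent <- matrix(stats::rnorm(max(config$n_modules, 1L) * n), ncol = n)
  if (config$n_modules > 0L && config$trait_coupling != 0) {
    latent[1L, ] <- latent[1L, ] + config$trait_coupling * (trait - 0.5)
  }

  n_de <- round(config$frac_de * p)
  if (config$frac_de > 0 && n_de < 1L) {
    warning("frac_de * n_proteins < 1; simulating zero differential proteins")
  }
  de_labels <- rep("null", p)
  effects <- numeric(p)
  if (n_de >= 1L) {
    # differential proteins live outside the modules: module members carry
    # their own trait response through trait_coupling on the module factor
    outside <- which(module_labels == 0L)
    take <- if (n_de <= length(outside)) sample(outside, n_de) else outside
    sgn <- sample(c(-1, 1), length(take), replace = TRUE)
    de_labels[take] <- ifelse(sgn > 0, "up", "down")
    effects[take] <- sgn * config$effect_log2fc
  }

  batch_offsets <- stats::rnorm(max(batch), 0, config$batch_effect_sd)
  x <- matrix(baseline, nrow = p, ncol = n)
  if (config$n_modules > 0L) {
    has_mod <- module_labels > 0L
    x[has_mod, ] <- x[has_mod, ] +
      loadings[has_mod] * latent[module_labels[has_mod], , drop = FALSE]
  }
  x <- x + outer(effects, trait) +
    matrix(batch_offsets[batch], nrow = p, ncol = n, byrow = TRUE) +
    matrix(stats::rnorm(p * n, 0, config$noise_sd), nrow = p)
  dimnames(x) <- list(protein_id, metadata$sample)
  x <- .insert_missing(x, config$missing_rate, config$missing_mechanism)

  list(
    matrix = x,
    metadata = metadata,
    truth = list(
      de_labels = stats::setNames(de_labels, protein_id),
      effects = stats::setNames(effects, protein_id),
      module_labels = stats::setNames(module_labels, protein_id),
      latent_factors = latent,
      loadings = stats::setNames(loadings, protein_id),
      batch_offsets = batch_offsets
    )
  )
}

.insert_missing <- function(x, rate, mechanism) {
  if (rate <= 0) return(x)
  n_cells <- length(x)
  n_miss <- round(rate * n_cells)
  if (n_miss < 1L) return(x)
  if (mechanism == "mcar") {
    idx <- sample.int(n_cells, n_miss)
  } else {
    # left-censored: missingness probability decreasing in intensity rank
    pr <- 2 * (1 - (rank(x, ties.method = "average") - 0.5) / n_cells)
    idx <- sample.int(n_cells, n_miss, prob = pr)
  }
  x[idx] <- NA_real_
  x
}

#' Simulate a phosphoproteome linked to a simulated proteome
#'
#' Each site gets a parent protein; a designated subset are true substrates
#' of the simulated kinases, with sequence windows sampled from the cognate
#' PSSM (background composition otherwise). Site log2 intensity = parent
#' protein intensity + a site-specific offset + kinase activity shift (mutant
#' samples of substrates of shifted kinases) + site-level noise, so that
#' protein-level normalization is meaningful by construction.
#'
#' @param config a [sim_config()].
#' @param proteome result of [simulate_proteome()].
#' @param kinase_models result of [simulate_kinase_models()]; simulated when
#'   omitted.
#' @return list with `matrix` (sites x samples), `site_table` (site_id,
#'   protein_id, residue, position, window15), `annotation` (kinase, site_id;
#'   the "known" substrate table) and `truth` (substrate_map, kinase_shifts).
#' @export
simulate_phosphoproteome <- function(config, proteome,
                                     kinase_models = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_phosphosites < 1L) stop("n_phosphosites must be >= 1")
  if (is.null(kinase_models)) kinase_models <- simulate_kinase_models(config)
  set.seed(.stage_seed(config$seed, 3L))
  ns <- config$n_phosphosites
  n <- ncol(proteome$matrix)
  trait <- proteome$metadata$trait

  parent <- sample(rownames(proteome$matrix), ns, replace = TRUE)

  # assign true substrates: disjoint blocks of sites per kinase
  n_sub <- min(config$n_substrates_per_kinase,
               floor(ns / max(config$n_kinases, 1L)))
  site_kinase <- rep(NA_character_, ns)
  pool <- sample.int(ns)
  kin_names <- names(kinase_models)
  for (i in seq_along(kin_names)) {
    take <- pool[seq.int((i - 1L) * n_sub + 1L, i * n_sub)]
    site_kinase[take] <- kin_names[i]
  }

  windows <- character(ns)
  residues <- character(ns)
  bg_center_p <- stats::setNames(rep(0, 20), AA_ALPHABET)
  bg_center_p[c("S", "T", "Y")] <- c(0.45, 0.45, 0.10)
  for (i in seq_len(ns)) {
    use_motif <- !is.na(site_kinase[i]) &&
      stats::runif(1) < config$substrate_window_from_motif
    if (use_motif) {
      pssm <- kinase_models[[site_kinase[i]]]
      w <- vapply(seq_len(WINDOW_WIDTH), function(pos) {
        sample(AA_ALPHABET, 1L, prob = pssm[pos, ])
      }, character(1))
    } else {
      w <- sample(AA_ALPHABET, WINDOW_WIDTH, replace = TRUE)
      w[WINDOW_CENTER] <- sample(AA_ALPHABET, 1L, prob = bg_center_p)
    }
    windows[i] <- paste(w, collapse = "")
    residues[i] <- w[WINDOW_CENTER]
  }
  position <- sample.int(800L, ns, replace = TRUE)
  site_id <- sprintf("%s;%s%d", parent, residues, position)
  # guarantee uniqueness (duplicate protein/residue/position draws)
  dup <- duplicated(site_id)
  while (any(dup)) {
    position[dup] <- sample.int(800L, sum(dup), replace = TRUE)
    site_id <- sprintf("%s;%s%d", parent, residues, position)
    dup <- duplicated(site_id)
  }

  shift <- stats::setNames(config$kinase_shift[seq_along(kin_names)],
                           kin_names)
  site_shift <- ifelse(is.na(site_kinase), 0, shift[site_kinase])
  offset <- stats::rnorm(ns, 0, 1)

  x <- proteome$matrix[parent, , drop = FALSE]
  x[is.na(x)] <- 20  # parent intensity missing: fall back to a flat baseline
  x <- x + offset +
    outer(site_shift * config$noise_sd, trait) +
    matrix(stats::rnorm(ns * n, 0, config$site_noise_sd), nrow = ns)
  dimnames(x) <- list(site_id, proteome$metadata$sample)
  x <- .insert_missing(x, config$missing_rate, config$missing_mechanism)

  substrate_map <- lapply(stats::setNames(kin_names, kin_names),
                          function(k) site_id[which(site_kinase == k)])
  annotation <- do.call(rbind, lapply(kin_names, function(k) {
    ann <- sample(substrate_map[[k]],
                  min(config$n_annotated_per_kinase,
                      length(substrate_map[[k]])))
    data.frame(kinase = k, site_id = ann, stringsAsFactors = FALSE)
  }))

  list(
    matrix = x,
    site_table = data.frame(
      site_id = site_id, protein_id = parent, residue = residues,
      position = position, window15 = windows, stringsAsFactors = FALSE
    ),
    annotation = annotation,
    truth = list(substrate_map = substrate_map, kinase_shifts = shift)
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_kinase_models()],
#' [simulate_proteome()] and [simulate_phosphoproteome()] in order.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `kinase_models`, `proteome`, `phospho`.
#' @export
simulate_study <- function(config = sim_config()) {
  kin <- simulate_kinase_models(config)
  prot <- simulate_proteome(config)
  phos <- simulate_phosphoproteome(config, prot, kin)
  list(config = config, kinase_models = kin, proteome = prot, phospho = phos)
}
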