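#' Select stably phosphorylated sites
#'
#' After median-centering each sample, returns the `fraction` of sites with
#' the lowest across-sample variance. These serve as negative-control anchors
#' for batch correction: their abundance is assumed constant across
#' conditions, so residual between-batch differences on them estimate the
#' technical offset.
#'
#' @param x log2 phosphosite matrix (>= 100 sites).
#' @param fraction fraction of sites to return, in (0, 1\] (default 0.1).
#' @return character vector of site ids, most stable first.
#' @export
select_stable_sites <- function(x, fraction = 0.1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (nrow(x) < 100L) stop("select_stable_sites() expects >= 100 sites")
  centered <- sweep(x, 2L, apply(x, 2L, stats::median, na.rm = TRUE), "-")
  v <- apply(centered, 1L, stats::var, na.rm = TRUE)
  n_take <- max(1L, ceiling(fraction * nrow(x)))
  names(sort(v))[seq_len(n_take)]
}

#' Batch correction anchored on stable sites
#'
#' Columns are median-centered per sample, then the batch-specific mean
#' computed on the stable sites is removed from every value of that batch's
#' samples. Group effects on non-stable sites are preserved because the
#' offset is estimated only on sites assumed condition-invariant. With a
#' single batch the matrix is returned unchanged. The correction is exactly
#' idempotent.
#'
#' @param x log2 phosphosite matrix.
#' @param batches batch label per sample.
#' @param stable_sites site ids from [select_stable_sites()].
#' @return corrected matrix.
#' @export
batch_correct <- function(x, batches, stable_sites) {
  batches <- as.factor(batches)
  stopifnot(length(batches) == ncol(x))
  if (nlevels(batches) < 2L) return(x)
  if (any(table(batches) == 0L)) stop("every batch needs at least one sample")
  stable_sites <- intersect(stable_sites, rownames(x))
  if (!length(stable_sites)) stop("no stable sites present in the matrix")
  centered <- sweep(x, 2L, apply(x, 2L, stats::median, na.rm = TRUE), "-")
  for (b in levels(batches)) {
    cols <- which(batches == b)
    off <- mean(centered[stable_sites, cols], na.rm = TRUE)
    centered[, cols] <- centered[, cols] - off
  }
  centered
}

#' Normalize phosphosite changes by parent protein level
#'
#' On the log2 scale, normalizing a site against its parent protein is a
#' subtraction: `fc_norm = fc_site - fc_protein`. Significance is recomputed
#' by moderated t on the per-sample difference profiles (site minus protein),
#' so that shared protein-level variation cancels sample-wise. Sites whose
#' parent protein is not in the protein matrix keep their unnormalized fold
#' change and are flagged.
#'
#' @param phospho_x log2 phosphosite matrix.
#' @param protein_x log2 protein matrix (same samples, same column order).
#' @param site_table data.frame with `site_id`, `protein_id` linking rows of
#'   `phospho_x` to rows of `protein_x`.
#' @param groups two-level factor of sample groups.
#' @return list with `stats` (site_id, protein_id, fc_site, fc_norm, t_mod,
#'   p, q_bh, normalized flag) and `diff_matrix` (per-sample site - protein
#'   profiles; unnormalized sites keep their site profile).
#' @export
normalize_site_by_protein <- function(phospho_x, protein_x, site_table,
                                      groups) {
  groups <- .assert_two_groups(groups)
  stopifnot(ncol(phospho_x) == ncol(protein_x))
  site_table <- site_table[match(rownames(phospho_x), site_table$site_id), ]
  if (anyNA(site_table$site_id)) {
    stop("every row of phospho_x must appear in site_table$site_id")
  }
  has_parent <- site_table$protein_id %in% rownames(protein_x)
  d <- phospho_x
  d[has_parent, ] <- phospho_x[has_parent, , drop = FALSE] -
    protein_x[site_table$protein_id[has_parent], , drop = FALSE]
  st <- moderated_t(d, groups)
  site_fc <- moderated_t(phospho_x, groups)$log2fc
  out <- data.frame(
    site_id = rownames(phospho_x),
    protein_id = site_table$protein_id,
    fc_site = site_fc,
    fc_norm = st$log2fc,
    t_mod = st$t_mod,
    p = st$p,
    q_bh = bh_adjust(st$p),
    normalized = has_parent,
    stringsAsFactors = FALSE
  )
  list(stats = out, diff_matrix = d)
}

#' Motif score of sequence windows against a kinase PSSM
#'
#' The raw score of a window is the mean log-odds over the 15 positions,
#' `mean(log(p_pos(aa) / q(aa)))` with background `q` (uniform by default).
#' Raw scores are mapped to \[0, 1\] as empirical percentiles within the
#' scored site set: `(average rank - 1) / (n - 1)` with ties receiving their
#' average rank, so the best window in a set scores exactly 1 and a fully
#' degenerate (uniform) motif gives 0.5 everywhere.
#'
#' @param windows character vector of 15-residue windows.
#' @param pssm 15 x 20 probability matrix (rows = positions, columns must be
#'   the 20-residue alphabet).
#' @param background named vector of background residue probabilities
#'   (default uniform 1/20).
#' @return data.frame with `raw` log-odds scores and `score` percentiles.
#' @export
motif_score <- function(windows, pssm,
                        background = stats::setNames(rep(1 / 20, 20),
                                                     AA_ALPHABET)) {
  stopifnot(nrow(pssm) == WINDOW_WIDTH, ncol(pssm) == 20)
  if (any(nchar(windows) != WINDOW_WIDTH)) {
    stop("all windows must have exactly ", WINDOW_WIDTH, " residues")
  }
  chars <- matrix(unlist(strsplit(windows, "")), ncol = WINDOW_WIDTH,
                  byrow = TRUE)
  idx <- match(chars, colnames(pssm))
  if (anyNA(idx)) {
    warning("unknown residue character(s) scored with background probability")
  }
  pmat <- matrix(NA_real_, nrow = nrow(chars), ncol = WINDOW_WIDTH)
  qmat <- matrix(background[match(chars, names(background))],
                 nrow = nrow(chars))
  qmat[is.na(qmat)] <- 1 / 20
  for (j in seq_len(WINDOW_WIDTH)) {
    aa <- match(chars[, j], colnames(pssm))
    pj <- ifelse(is.na(aa), qmat[, j], pssm[j, ifelse(is.na(aa), 1L, aa)])
    pmat[, j] <- pmax(pj, 1e-9)  # floor zero-probability residues
  }
  raw <- rowMeans(log(pmat / qmat))
  n <- length(raw)
  score <- if (n == 1L) 0.5 else (rank(raw, ties.method = "average") - 1) / (n - 1)
  data.frame(raw = raw, score = score)
}

#' Dynamics (profile) score of sites against a kinase centroid
#'
#' Pearson correlation between each standardized site profile and the kinase
#' centroid, rescaled to \[0, 1\] as `(r + 1) / 2`. Zero-variance profiles
#' get score 0.5 and are flagged in the `flat` attribute.
#'
#' @param profiles sites x samples matrix of phosphorylation dynamics
#'   (standardized internally).
#' @param centroid numeric vector, the kinase's standardized mean substrate
#'   profile (length = number of samples).
#' @return numeric vector of scores in \[0, 1\], one per row of `profiles`,
#'   with attribute `flat` marking zero-variance profiles.
#' @export
profile_score <- function(profiles, centroid) {
  stopifnot(ncol(profiles) == length(centroid), ncol(profiles) >= 3L)
  z <- .row_standardize(profiles)
  csd <- stats::sd(centroid)
  if (!is.finite(csd) || csd == 0) {
    out <- rep(0.5, nrow(profiles))
    attr(out, "flat") <- rep(TRUE, nrow(profiles))
    return(out)
  }
  cz <- (centroid - mean(centroid)) / csd
  r <- as.vector(z %*% cz) / ((length(centroid) - 1))
  flat <- apply(profiles, 1L, stats::sd) == 0
  r[flat] <- 0
  out <- (pmin(pmax(r, -1), 1) + 1) / 2
  out[flat] <- 0.5
  attr(out, "flat") <- flat
  out
}

#' Combine motif and profile scores
#'
#' Weighted geometric mean `motif^w * profile^(1-w)`; monotone in both
#' arguments, equal to the plain geometric mean at `w = 0.5`.
#'
#' @param motif,profile scores in \[0, 1\].
#' @param w motif weight in \[0, 1\] (default 0.5).
#' @return combined scores in \[0, 1\].
#' @export
combined_substrate_score <- function(motif, profile, w = 0.5) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  motif^w * profile^(1 - w)
}

#' Adaptive positive-unlabeled substrate prediction
#'
#' Known (annotated) substrates are the positives; all other sites are
#' unlabeled. Over `n_rounds` rounds, pseudo-negatives are sampled from the
#' unlabeled sites with probability proportional to `(1 - combined score)`
#' times an adaptive weight, a ridge-regularized logistic classifier is fit
#' on (motif, profile, combined), and all sites are scored. The adaptive
#' weight is updated after each round to down-weight sites the current
#' ensemble scores high (they are likely unannotated substrates, not
#' negatives). The PU probability of a site is its mean predicted
#' positive-class probability across rounds.
#'
#' @param scores data.frame with columns `site_id`, `motif`, `profile`,
#'   `combined` for one kinase.
#' @param positives character vector of annotated substrate site ids
#'   (>= 5 required for the classifier; fewer falls back to the combined
#'   score with a warning).
#' @param n_rounds ensemble size (default 50).
#' @param seed integer seed.
#' @param lambda ridge penalty of the logistic classifier.
#' @return numeric vector of PU probabilities, one per row of `scores`.
#' @export
pu_predict <- function(scores, positives, n_rounds = 50L, seed = 1L,
                       lambda = 0.01) {
  stopifnot(all(c("site_id", "motif", "profile", "combined") %in%
                  names(scores)))
  pos <- scores$site_id %in% positives
  n_pos <- sum(pos)
  if (n_pos < 5L) {
    warning("fewer than 5 annotated positives; ",
            "falling back to ranking by combined score")
    return(scores$combined)
  }
  set.seed(seed)
  X <- as.matrix(scores[, c("motif", "profile", "combined")])
  unl <- which(!pos)
  acc <- numeric(nrow(scores))
  adapt <- rep(1, length(unl))
  for (b in seq_len(n_rounds)) {
    w_neg <- (1 - scores$combined[unl]) * adapt
    if (all(w_neg <= 0)) w_neg <- rep(1, length(unl))
    neg <- sample(unl, size = min(n_pos, length(unl)), prob = w_neg)
    train <- c(which(pos), neg)
    y <- c(rep(1L, n_pos), rep(0L, length(neg)))
    fit <- glmnet::glmnet(X[train, , drop = FALSE], y, family = "binomial",
                          alpha = 0, lambda = lambda, standardize = TRUE)
    pr <- as.vector(stats::predict(fit, newx = X, type = "response"))
    acc <- acc + pr
    adapt <- 1 - (acc[unl] / b)  # down-weight currently high-scoring sites
    adapt <- pmax(adapt, 1e-6)
  }
  acc / n_rounds
}

#' Kinase-substrate scoring across all sites and kinases
#'
#' For each kinase: motif percentiles of every window against the kinase
#' PSSM, dynamics correlation against the centroid of the kinase's annotated
#' substrates (standardized mean profile), their geometric-mean combination,
#' and the adaptive PU probability.
#'
#' @param profiles sites x samples matrix used for dynamics (typically the
#'   protein-normalized difference profiles).
#' @param site_table data.frame with `site_id`, `window15`.
#' @param kinase_models named list of PSSMs (see [simulate_kinase_models()]
#'   for the layout).
#' @param annotation data.frame with `kinase`, `site_id` (known substrates).
#' @param w motif weight for the combination.
#' @param n_rounds,seed,lambda passed to [pu_predict()].
#' @return data.frame with site_id, kinase, motif, profile, combined,
#'   pu_probability, rank (within kinase by PU probability).
#' @export
kinase_substrate_score <- function(profiles, site_table, kinase_models,
                                   annotation, w = 0.5, n_rounds = 50L,
                                   seed = 1L, lambda = 0.01) {
  site_table <- site_table[match(rownames(profiles), site_table$site_id), ]
  z <- .row_standardize(profiles)
  out <- lapply(names(kinase_models), function(k) {
    ms <- motif_score(site_table$window15, kinase_models[[k]])$score
    ann <- annotation$site_id[annotation$kinase == k]
    ann <- intersect(ann, rownames(profiles))
    if (length(ann) == 0L) {
      stop("kinase ", k, " has no annotated substrates in the matrix")
    }
    centroid <- colMeans(z[ann, , drop = FALSE])
    if (stats::sd(centroid) > 0) {
      centroid <- (centroid - mean(centroid)) / stats::sd(centroid)
    }
    ps <- profile_score(profiles, centroid)
    df <- data.frame(
      site_id = rownames(profiles), kinase = k,
      motif = ms, profile = as.numeric(ps),
      combined = combined_substrate_score(ms, as.numeric(ps), w),
      stringsAsFactors = FALSE
    )
    df$pu_probability <- pu_predict(df, ann, n_rounds = n_rounds,
                                    seed = .stage_seed(seed, match(k, names(kinase_models))),
                                    lambda = lambda)
    df
  })
  out <- do.call(rbind, out)
  out$rank <- stats::ave(-out$pu_probability, out$kinase,
                         FUN = function(v) rank(v, ties.method = "first"))
  out
}

#' Top-N predicted substrates of a kinase
#'
#' Sites sorted by the ranking key descending, ties broken by motif score
#' (descending) then site id (lexicographic), making the ordering fully
#' deterministic.
#'
#' @param scores data.frame from [kinase_substrate_score()].
#' @param kinase kinase name.
#' @param n number of sites (default 400, the conventional depth for the
#'   primary kinase of interest; 200 is typical otherwise).
#' @param key `"pu_probability"` or `"combined"`.
#' @return character vector of site ids, best first.
#' @export
rank_top_substrates <- function(scores, kinase, n = 400L,
                                key = c("pu_probability", "combined")) {
  key <- match.arg(key)
  if (n <= 0L) stop("n must be positive")
  sub <- scores[scores$kinase == kinase, ]
  if (!nrow(sub)) stop("no scored sites for kinase ", kinase)
  n <- min(n, nrow(sub))
  ord <- order(-sub[[key]], -sub$motif, sub$site_id)
  sub$site_id[ord][seq_len(n)]
}

#' Kinase activity from predicted substrates
#'
#' The activity score is the mean standardized protein-normalized fold
#' change (z relative to all scored sites) over the kinase's top predicted
#' substrates; the p-value is a one-sample t-test of the substrates'
#' `fc_norm` against zero, and the direction follows the sign of the
#' activity score at `p < p_cut`.
#'
#' @param norm_stats `stats` data.frame from [normalize_site_by_protein()].
#' @param substrates character vector of substrate site ids.
#' @param kinase kinase name carried into the output.
#' @param p_cut significance cutoff for calling a direction (default 0.05).
#' @return one-row data.frame: kinase, activity_score, p, direction,
#'   n_substrates.
#' @export
kinase_activity <- function(norm_stats, substrates, kinase = NA_character_,
                            p_cut = 0.05) {
  if (!length(substrates)) stop("substrate set is empty")
  idx <- match(substrates, norm_stats$site_id)
  idx <- idx[!is.na(idx)]
  fc <- norm_stats$fc_norm[idx]
  mu <- mean(norm_stats$fc_norm, na.rm = TRUE)
  s <- stats::sd(norm_stats$fc_norm, na.rm = TRUE)
  z <- if (is.finite(s) && s > 0) (fc - mu) / s else fc * 0
  activity <- mean(z)
  p <- if (length(fc) < 3L || stats::sd(fc) == 0) {
    NA_real_
  } else {
    stats::t.test(fc, mu = 0)$p.value
  }
  direction <- if (is.na(p) || p >= p_cut || activity == 0) {
    "unchanged"
  } else if (activity > 0) "up" else "down"
  data.frame(kinase = kinase, activity_score = activity, p = p,
             direction = direction, n_substrates = length(fc),
             stringsAsFactors = FALSE)
}

#' Map detected phosphosites onto annotated consensus substrates
#'
#' Intersects the detected sites with the annotated substrates of a query
#' kinase and classifies each matched site as trending up, trending down or
#' flat using a relaxed rule (default FDR < 0.2 and |fc| > 1 x fitted SD),
#' the convention for consensus-substrate trend calling.
#'
#' @param stats data.frame with `site_id`, a fold-change column
#'   (`fc_norm` preferred, else `log2fc`), and `q_bh`.
#' @param annotation data.frame with `kinase`, `site_id`.
#' @param kinase query kinase.
#' @param sd_hat fitted fold-change SD.
#' @param fdr_cut FDR cutoff (default 0.2).
#' @param sd_multiple fold-change threshold multiple (default 1; 0 collapses
#'   the threshold so every FDR-passing site is classified by sign).
#' @return list with `sites` (site_id, fc, q_bh, class) and `counts`
#'   (n_matched, n_up, n_down, n_flat).
#' @export
map_consensus_substrates <- function(stats, annotation, kinase, sd_hat,
                                     fdr_cut = 0.2, sd_multiple = 1) {
  ann <- annotation$site_id[annotation$kinase == kinase]
  fc_col <- if ("fc_norm" %in% names(stats)) "fc_norm" else "log2fc"
  matched <- stats[stats$site_id %in% ann, c("site_id", fc_col, "q_bh")]
  names(matched)[2L] <- "fc"
  if (!nrow(matched)) {
    return(list(sites = matched,
                counts = c(n_matched = 0L, n_up = 0L, n_down = 0L,
                           n_flat = 0L)))
  }
  thr <- sd_multiple * sd_hat
  cls <- rep("flat", nrow(matched))
  sig <- !is.na(matched$q_bh) & matched$q_bh < fdr_cut
  cls[sig & matched$fc > thr] <- "trend_up"
  cls[sig & matched$fc < -thr] <- "trend_down"
  matched$class <- cls
  list(sites = matched,
       counts = c(n_matched = nrow(matched),
                  n_up = sum(cls == "trend_up"),
                  n_down = sum(cls == "trend_down"),
                  n_flat = sum(cls == "flat")))
}
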