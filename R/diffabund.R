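#' Preprocess a raw intensity matrix
#'
#' Log2 transformation (optional), per-feature missing-value imputation and
#' filtering of features with too few observed values per group. The chosen
#' options are recorded in the `"preprocess"` attribute of the result so that
#' downstream provenance sidecars can reproduce the run.
#'
#' @param x numeric matrix, features x samples. Raw nonnegative intensities
#'   unless `already_log2 = TRUE`; zeros are treated as missing.
#' @param groups two-level factor/character vector of sample groups.
#' @param already_log2 set `TRUE` when `x` is already on the log2 scale.
#' @param imputation one of `"half_min"` (per-feature observed minimum minus
#'   one log2 unit, i.e. half the minimum intensity), `"feature_min"`,
#'   `"group_min"` or `"none"`.
#' @param min_nonmissing_per_group drop features observed fewer times than
#'   this in either group (before imputation).
#' @return log2 matrix with attributes `preprocess` (options) and
#'   `dropped` (ids of removed features).
#' @export
preprocess <- function(x, groups, already_log2 = FALSE,
                       imputation = c("half_min", "feature_min",
                                      "group_min", "none"),
                       min_nonmissing_per_group = 2L) {
  imputation <- match.arg(imputation)
  groups <- .assert_two_groups(groups)
  stopifnot(is.matrix(x), ncol(x) == length(groups))
  if (!already_log2) {
    if (any(x < 0, na.rm = TRUE)) {
      stop("raw intensities must be nonnegative (or pass already_log2 = TRUE)")
    }
    x[!is.na(x) & x == 0] <- NA_real_
    x <- log2(x)
  }

  obs <- !is.na(x)
  lev <- levels(groups)
  n1 <- rowSums(obs[, groups == lev[1L], drop = FALSE])
  n2 <- rowSums(obs[, groups == lev[2L], drop = FALSE])
  keep <- n1 >= min_nonmissing_per_group & n2 >= min_nonmissing_per_group
  dropped <- rownames(x)[!keep]
  if (length(dropped)) {
    warning(length(dropped), " feature(s) dropped: fewer than ",
            min_nonmissing_per_group, " observed values in a group")
  }
  x <- x[keep, , drop = FALSE]

  if (imputation != "none" && anyNA(x)) {
    x <- switch(imputation,
      half_min = .impute_rowwise(x, function(row, g) min(row, na.rm = TRUE) - 1),
      feature_min = .impute_rowwise(x, function(row, g) min(row, na.rm = TRUE)),
      group_min = .impute_group_min(x, groups)
    )
  }
  attr(x, "preprocess") <- list(
    already_log2 = already_log2, imputation = imputation,
    min_nonmissing_per_group = min_nonmissing_per_group,
    n_dropped = length(dropped)
  )
  attr(x, "dropped") <- dropped
  x
}

.impute_rowwise <- function(x, fill_fun) {
  for (i in which(rowSums(is.na(x)) > 0L)) {
    x[i, is.na(x[i, ])] <- fill_fun(x[i, ], NULL)
  }
  x
}

.impute_group_min <- function(x, groups) {
  for (g in levels(groups)) {
    cols <- which(groups == g)
    for (i in seq_len(nrow(x))) {
      miss <- cols[is.na(x[i, cols])]
      if (length(miss)) {
        gm <- suppressWarnings(min(x[i, cols], na.rm = TRUE))
        if (!is.finite(gm)) gm <- min(x[i, ], na.rm = TRUE)
        x[i, miss] <- gm
      }
    }
  }
  x
}

# Per-feature two-group summary statistics with NA-aware counts.
.group_stats <- function(x, idx1, idx2) {
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / pmax(df, 1)
  list(n1 = n1, n2 = n2, mean1 = m1, mean2 = m2, s2 = s2, df = df)
}

# Newton inversion of the trigamma function (used by the moment-matching
# estimator of the variance-prior degrees of freedom).
.trigamma_inverse <- function(y) {
  out <- y
  pos <- is.finite(y) & y > 0
  out[!pos & is.finite(y)] <- Inf
  x <- 0.5 + 1 / y[pos]
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[pos]) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[pos] <- x
  out
}

#' Empirical-Bayes moderated t-statistics for a two-group comparison
#'
#' Per-feature pooled residual variances are shrunk towards a common prior
#' estimated by moment matching on the log variances (digamma/trigamma
#' inversion): the prior degrees of freedom d0 solve
#' `trigamma(d0/2) = var(e) - trigamma(d/2)` with
#' `e = log(s2) - digamma(d/2) + log(d/2)`, and the prior variance is
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. The posterior variance
#' is `(d0*s0^2 + d*s2) / (d0 + d)` and the moderated t is referenced to a
#' t-distribution with `d0 + d` degrees of freedom. When the observed
#' variances show no excess dispersion the prior degrees of freedom are
#' capped at a large finite value (complete shrinkage), with a message.
#'
#' @param x log2 intensity matrix, features x samples.
#' @param groups two-level factor; the log2 fold change is
#'   `second level - first level` (e.g. mutant - control).
#' @return data.frame: feature_id, mean per group, log2fc, s2, s2_post,
#'   df_prior, df_total, t_mod, p.
#' @export
moderated_t <- function(x, groups) {
  groups <- .assert_two_groups(groups)
  lev <- levels(groups)
  gs <- .group_stats(x, which(groups == lev[1L]), which(groups == lev[2L]))
  if (any(gs$n1 < 2L) || any(gs$n2 < 2L)) {
    stop("moderated_t() needs >= 2 observed values per group for every feature")
  }
  if (all(gs$df <= 0)) stop("zero residual degrees of freedom")
  fit <- .fit_variance_prior(gs$s2, gs$df)
  s2_post <- (fit$d0 * fit$s0_2 + gs$df * gs$s2) / (fit$d0 + gs$df)
  se <- sqrt(s2_post * (1 / gs$n1 + 1 / gs$n2))
  log2fc <- gs$mean2 - gs$mean1
  t_mod <- log2fc / se
  df_total <- fit$d0 + gs$df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(
    feature_id = rownames(x),
    mean_1 = gs$mean1, mean_2 = gs$mean2,
    log2fc = log2fc, s2 = gs$s2, s2_post = s2_post,
    df_prior = fit$d0, df_total = df_total,
    t_mod = t_mod, p = p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  names(out)[2:3] <- paste0("mean_", lev)
  out
}

# Moment-matching fit of the scaled inverse chi-square variance prior.
.fit_variance_prior <- function(s2, df, d0_cap = 1e6) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) {
    return(list(d0 = d0_cap, s0_2 = stats::median(s2[s2 > 0], na.rm = TRUE)))
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(df[ok] / 2))
  if (!is.finite(excess) || excess <= 0) {
    message("no excess variance dispersion; prior df capped at ", d0_cap)
    d0 <- d0_cap
    s0_2 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(excess)
    if (!is.finite(d0) || d0 > d0_cap) {
      message("prior df capped at ", d0_cap)
      d0 <- d0_cap
    }
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Gaussian SD fitted to the bulk of a log2 fold-change distribution
#'
#' The fold-change threshold unit of the pipeline: the SD of a Gaussian fitted
#' to the central bulk of the log2FC distribution, robust to the minority of
#' truly differential features in the tails. The default `"gaussian"` method
#' is an iteratively truncated maximum-likelihood fit: starting from
#' median/MAD, values within `median +/- 2.576 sd` are kept, the ML SD of the
#' retained values is corrected for truncation bias, and the window is
#' re-derived until convergence. `"trimmed"` is a single ML fit to values
#' within the 1st-99th percentile (also bias-corrected), `"plain"` the sample
#' SD, `"mad"` the scaled median absolute deviation.
#'
#' @param log2fc numeric vector of fold changes (>= 50 finite values).
#' @param method fitting variant, see above.
#' @return the fitted SD (single number).
#' @export
fit_fc_sd <- function(log2fc,
                      method = c("gaussian", "trimmed", "plain", "mad")) {
  method <- match.arg(method)
  v <- log2fc[is.finite(log2fc)]
  if (length(v) < 50L) {
    stop("fit_fc_sd() needs >= 50 finite fold changes; ",
         "supply the SD explicitly for smaller inputs")
  }
  if (all(v == 0)) {
    warning("all fold changes are zero; returning sd = 0")
    return(0)
  }
  switch(method,
    plain = stats::sd(v),
    mad = stats::mad(v),
    trimmed = {
      q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
      kept <- v[v >= q[1L] & v <= q[2L]]
      .truncated_sd(kept, c = stats::qnorm(0.99))
    },
    gaussian = {
      mu <- stats::median(v)
      s <- stats::mad(v)
      if (s == 0) s <- stats::sd(v)
      cc <- stats::qnorm(0.995)  # 99% central coverage window
      for (i in seq_len(100L)) {
        kept <- v[abs(v - mu) < cc * s]
        if (length(kept) < 10L) break
        mu_new <- mean(kept)
        s_new <- .truncated_sd(kept, c = cc, center = mu_new)
        if (!is.finite(s_new) || s_new == 0) break
        done <- abs(s_new - s) < 1e-8 * max(s, 1e-12)
        mu <- mu_new
        s <- s_new
        if (done) break
      }
      s
    }
  )
}

# ML SD of a sample assumed truncated at center +/- c standard deviations,
# corrected for the variance lost to truncation.
.truncated_sd <- function(v, c, center = mean(v)) {
  raw <- sqrt(mean((v - center)^2))
  corr <- sqrt(1 - 2 * c * stats::dnorm(c) / (2 * stats::pnorm(c) - 1))
  raw / corr
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with monotonicity enforcement. `NA` p-values
#' propagate as `NA` and are excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return adjusted p-values (q-values), same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Threshold specification for differential calls
#'
#' Two alternative selection rules are supported, both requiring the absolute
#' log2 fold change to exceed `sd_multiple` times the fitted Gaussian SD:
#' `"fdr_and_fc"` gates on BH FDR (`q < fdr_cut`), `"p_and_fc_permgate"`
#' gates on the raw p-value (`p < p_cut`) with set-level significance judged
#' afterwards by permutation FDR (see [permutation_fdr()]).
#'
#' @param fdr_cut BH FDR cutoff (default 0.05).
#' @param p_cut raw p-value cutoff (default 0.05).
#' @param sd_multiple fold-change threshold in fitted-SD units (k in
#'   `|log2FC| > k*SD`; conventional values 1, 1.5 or 2).
#' @param mode `"fdr_and_fc"` or `"p_and_fc_permgate"`.
#' @return an object of class `threshold_spec`.
#' @export
threshold_spec <- function(fdr_cut = 0.05, p_cut = 0.05, sd_multiple = 2,
                           mode = c("fdr_and_fc", "p_and_fc_permgate")) {
  mode <- match.arg(mode)
  if (sd_multiple <= 0) stop("sd_multiple must be > 0")
  structure(list(fdr_cut = fdr_cut, p_cut = p_cut,
                 sd_multiple = sd_multiple, mode = mode),
            class = "threshold_spec")
}

#' Call differential features from moderated statistics
#'
#' A feature is called `up` when `log2fc > k*sd_hat` (strict) and the
#' significance gate of the [threshold_spec()] passes, `down` when
#' `log2fc < -k*sd_hat` with the gate, `null` otherwise. Fold changes exactly
#' at the threshold are not called.
#'
#' @param stats data.frame from [moderated_t()]; a `q_bh` column is added
#'   when absent.
#' @param sd_hat fitted fold-change SD (> 0), see [fit_fc_sd()].
#' @param spec a [threshold_spec()].
#' @return `stats` with columns `q_bh` and `call`, plus a `summary`
#'   attribute (n_up, n_down, n_detected, sd_hat, spec).
#' @export
call_features <- function(stats, sd_hat, spec = threshold_spec()) {
  stopifnot(inherits(spec, "threshold_spec"), sd_hat > 0)
  if (is.null(stats$q_bh)) stats$q_bh <- bh_adjust(stats$p)
  gate <- switch(spec$mode,
    fdr_and_fc = stats$q_bh < spec$fdr_cut,
    p_and_fc_permgate = stats$p < spec$p_cut
  )
  gate[is.na(gate)] <- FALSE
  thr <- spec$sd_multiple * sd_hat
  call <- rep("null", nrow(stats))
  call[gate & stats$log2fc > thr] <- "up"
  call[gate & stats$log2fc < -thr] <- "down"
  stats$call <- call
  attr(stats, "summary") <- list(
    n_up = sum(call == "up"), n_down = sum(call == "down"),
    n_detected = sum(call != "null"), sd_hat = sd_hat, spec = spec
  )
  stats
}

# All balanced two-group label assignments (columns = assignments of the
# first-group sample indices); exhaustive when few, seeded sample otherwise.
.balanced_relabelings <- function(n, n1, n_perm) {
  n_total <- choose(n, n1)
  if (n_total <= n_perm) {
    utils::combn(n, n1)
  } else {
    m <- matrix(0L, nrow = n1, ncol = n_perm)
    for (b in seq_len(n_perm)) m[, b] <- sort(sample.int(n, n1))
    m
  }
}

#' Permutation-based FDR for a selected feature set
#'
#' The observed count O of features passing `p < p_cut` and
#' `|log2fc| > k * sd_hat` is compared with the counts obtained under
#' balanced group-label permutations, recomputing the moderated statistics
#' and refitting the fold-change SD within each permutation (so the null is
#' self-consistent). The FDR estimate is `mean(N_b) / max(O, 1)`; the
#' selected set is declared significant when the estimate falls below
#' `spec$fdr_cut`. All distinct balanced relabelings are enumerated when
#' there are at most `n_perm` of them (e.g. 20 for a 3 vs 3 design).
#'
#' @param x log2 intensity matrix.
#' @param groups two-level factor.
#' @param spec a [threshold_spec()] (its `p_cut`, `sd_multiple` and
#'   `fdr_cut` are used).
#' @param n_perm maximum number of permutations (default 1000).
#' @param seed integer seed for sampled permutations.
#' @param sd_method passed to [fit_fc_sd()].
#' @return list of class `permutation_fdr`: observed_count, null_counts,
#'   fdr_est (`NA` when no feature passes on the true labels), significant,
#'   n_perm, exhaustive, seed.
#' @export
permutation_fdr <- function(x, groups, spec = threshold_spec(),
                            n_perm = 1000L, seed = 1L,
                            sd_method = "gaussian") {
  groups <- .assert_two_groups(groups)
  if (ncol(x) < 4L) stop("permutation_fdr() needs at least 4 samples")
  if (n_perm < 10L) warning("n_perm < 10 gives an unstable FDR estimate")
  lev <- levels(groups)
  n1 <- sum(groups == lev[1L])
  count_passing <- function(idx1) {
    g <- factor(ifelse(seq_len(ncol(x)) %in% idx1, lev[1L], lev[2L]),
                levels = lev)
    st <- suppressMessages(moderated_t(x, g))
    sd_hat <- fit_fc_sd(st$log2fc, method = sd_method)
    if (sd_hat <= 0) return(0L)
    sum(st$p < spec$p_cut &
          abs(st$log2fc) > spec$sd_multiple * sd_hat, na.rm = TRUE)
  }
  observed <- count_passing(which(groups == lev[1L]))
  set.seed(seed)
  labelings <- .balanced_relabelings(ncol(x), n1, n_perm)
  null_counts <- apply(labelings, 2L, count_passing)
  fdr_est <- if (observed == 0L) NA_real_ else mean(null_counts) / observed
  structure(list(
    observed_count = observed,
    null_counts = null_counts,
    fdr_est = fdr_est,
    significant = is.finite(fdr_est) && fdr_est < spec$fdr_cut,
    n_perm = ncol(labelings),
    exhaustive = ncol(labelings) == choose(ncol(x), n1),
    seed = seed
  ), class = "permutation_fdr")
}

#' Full differential-abundance analysis of one dataset
#'
#' Moderated t-statistics, BH adjustment, Gaussian-SD fold-change threshold
#' and calls; optionally attaches the permutation FDR of the selected set
#' (always computed in `"p_and_fc_permgate"` mode, where the set-level gate
#' is part of the selection rule).
#'
#' @inheritParams permutation_fdr
#' @param run_permutation compute the permutation FDR (default: only in
#'   `p_and_fc_permgate` mode).
#' @return list of class `diffabund_result`: `stats` (with calls), `sd_hat`,
#'   `summary`, `permutation` (or `NULL`).
#' @export
diff_abundance <- function(x, groups, spec = threshold_spec(),
                           sd_method = "gaussian",
                           run_permutation = spec$mode == "p_and_fc_permgate",
                           n_perm = 1000L, seed = 1L) {
  groups <- .assert_two_groups(groups)
  st <- moderated_t(x, groups)
  st$q_bh <- bh_adjust(st$p)
  sd_hat <- fit_fc_sd(st$log2fc, method = sd_method)
  if (sd_hat <= 0) {
    warning("fitted fold-change SD is zero; no features can be called")
    sd_hat <- .Machine$double.eps
  }
  st <- call_features(st, sd_hat, spec)
  perm <- NULL
  if (run_permutation) {
    perm <- permutation_fdr(x, groups, spec, n_perm = n_perm, seed = seed,
                            sd_method = sd_method)
  } else if (spec$mode == "p_and_fc_permgate") {
    stop("p_and_fc_permgate mode requires the permutation FDR; ",
         "set run_permutation = TRUE")
  }
  structure(list(stats = st, sd_hat = sd_hat,
                 summary = attr(st, "summary"), permutation = perm),
            class = "diffabund_result")
}
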