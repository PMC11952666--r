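#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with Pearson correlation across
#' samples (pairwise-complete observations), so perfectly anti-correlated
#' features are unconnected; diagonal is 1.
#'
#' @param x features x samples matrix.
#' @param power soft-threshold exponent beta (>= 1).
#' @return features x features adjacency in \[0, 1\].
#' @export
signed_adjacency <- function(x, power) {
  if (power < 1) stop("power must be >= 1")
  v <- apply(x, 1L, stats::var, na.rm = TRUE)
  if (any(!is.finite(v) | v == 0)) {
    stop("zero-variance feature(s) present; drop them before ",
         "network construction")
  }
  cm <- stats::cor(t(x), use = "pairwise.complete.obs")
  a <- ((1 + cm) / 2)^power
  diag(a) <- 1
  a
}

#' Signed topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, where the neighbor sum excludes i and j and
#' `k_i = sum_{j != i} a_ij`; `TOM_ii = 1`. The corresponding dissimilarity
#' is `1 - TOM`.
#'
#' @param adjacency symmetric adjacency with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop("adjacency must be symmetric")
  }
  a <- adjacency
  diag(a) <- 1
  k <- rowSums(a) - 1
  num <- crossprod(a) - 2 * a + a     # shared neighbors (u != i, j) + a_ij
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# Scale-free fit of a connectivity vector: quantile-binned log-log
# regression of degree density on degree; signed R2 = -sign(slope) * R2.
.scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins) return(c(r2 = NA_real_, slope = NA_real_))
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3L) return(c(r2 = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  count <- tapply(k, bin, length)
  width <- diff(br)
  dens <- count / (length(k) * width)
  keep <- is.finite(mean_k) & dens > 0 & width > 0
  if (sum(keep) < 3L) return(c(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(dens[keep]) ~ log10(mean_k[keep]))
  c(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]))
}

#' Soft-threshold power selection for a signed network
#'
#' For each candidate power the signed adjacency is built, connectivities
#' are binned into 10 equal-occupancy bins and the log10 degree density is
#' regressed on log10 mean degree; the signed scale-free fit is
#' `-sign(slope) * R2`. The chosen power is the smallest one with signed R2
#' at or above `r2_target` and mean connectivity below `max_mean_k`. If no
#' power reaches the target, the first power at the R2 plateau (gain below
#' 0.01) is chosen with a warning.
#'
#' @param x features x samples matrix (constant features are dropped with a
#'   warning).
#' @param powers candidate powers (default 1:20).
#' @param r2_target signed scale-free R2 target (default 0.85).
#' @param max_mean_k mean-connectivity ceiling (default 100).
#' @return list of class `soft_threshold_scan`: `table` (power, signed_r2,
#'   slope, mean_k), `power`, `reached_target`.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, r2_target = 0.85,
                                max_mean_k = 100) {
  if (nrow(x) < 50L) stop("need >= 50 features")
  if (ncol(x) < 4L) stop("need >= 4 samples")
  v <- apply(x, 1L, stats::var, na.rm = TRUE)
  if (any(!is.finite(v) | v == 0)) {
    warning(sum(!is.finite(v) | v == 0), " constant feature(s) dropped")
    x <- x[is.finite(v) & v > 0, , drop = FALSE]
  }
  cm <- stats::cor(t(x), use = "pairwise.complete.obs")
  base <- (1 + cm) / 2
  diag(base) <- 0                     # connectivity excludes self
  tab <- data.frame(power = powers, signed_r2 = NA_real_,
                    slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(base^powers[i])
    sf <- .scale_free_fit(k)
    tab$signed_r2[i] <- -sign(sf[["slope"]]) * sf[["r2"]]
    tab$slope[i] <- sf[["slope"]]
    tab$mean_k[i] <- mean(k)
  }
  ok <- !is.na(tab$signed_r2) & tab$signed_r2 >= r2_target &
    tab$mean_k < max_mean_k
  if (any(ok)) {
    power <- tab$power[which(ok)[1L]]
    reached <- TRUE
  } else {
    gain <- c(Inf, diff(tab$signed_r2))
    best_r2 <- max(tab$signed_r2, na.rm = TRUE)
    # plateau of the asymptote: small gain AND near the best fit reached
    plateau <- which(!is.na(gain) & abs(gain) < 0.01 &
                       tab$signed_r2 >= best_r2 - 0.02)
    power <- if (length(plateau)) tab$power[plateau[1L]] else
      tab$power[which.max(tab$signed_r2)]
    reached <- FALSE
    warning("no power reached signed R2 >= ", r2_target,
            "; falling back to the R2 plateau at power ", power)
  }
  structure(list(table = tab, power = power, reached_target = reached),
            class = "soft_threshold_scan")
}

#' Detect modules by adaptive cutting of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity,
#' followed by an adaptive height cut: candidate cut heights (midpoints
#' between consecutive merge heights) are scanned, and the height producing
#' the largest number of valid branches is chosen (ties resolved towards the
#' higher, more inclusive cut). A branch is valid when it has at least
#' `min_size` members and is coherent, i.e. its mean internal dissimilarity
#' is below `coherence` times the cut height — this rejects loose clumps of
#' background features that merge just below the cut. No PAM-style
#' reassignment is performed, so assignments adhere strictly to the
#' dendrogram. Features outside valid branches are unassigned (label 0).
#' Fully degenerate input (all pairwise dissimilarities equal) returns all
#' labels 0.
#'
#' @param diss TOM dissimilarity matrix (values in \[0, 1\]).
#' @param min_size minimum module size (default 50).
#' @param coherence internal-tightness factor in (0, 1\] (default 0.9).
#' @param similarity optional direct similarity matrix (typically the signed
#'   adjacency) used for the per-branch refinement; defaults to `1 - diss`.
#' @return integer labels per feature (named); 0 = unassigned; modules are
#'   numbered by decreasing size. The chosen cut height and the dendrogram
#'   are attached as attributes `cut_height` and `dendro`.
#' @export
detect_modules <- function(diss, min_size = 50L, coherence = 0.9,
                           similarity = NULL) {
  if (is.null(similarity)) similarity <- 1 - diss
  stopifnot(isSymmetric(unname(diss), tol = 1e-8))
  n <- nrow(diss)
  labels <- stats::setNames(integer(n), rownames(diss))
  if (min_size > n) {
    warning("min_size exceeds the number of features; all unassigned")
    return(labels)
  }
  off <- diss[upper.tri(diss)]
  if (length(unique(round(off, 12L))) == 1L) {
    return(labels)                     # degenerate: no structure
  }
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  hts <- sort(unique(hc$height))
  cuts <- if (length(hts) > 1L) {
    (utils::head(hts, -1L) + utils::tail(hts, -1L)) / 2
  } else {
    hts / 2
  }
  # keep the scan tractable on large dendrograms
  if (length(cuts) > 64L) {
    cuts <- unique(stats::quantile(cuts, probs = seq(0, 1, length.out = 64L),
                                   names = FALSE, type = 1L))
  }
  # also consider a cut above the top merge (single root cluster)
  cuts <- c(cuts, max(hts) * 1.01)
  best <- list(count = -1L, covered = -1L, h = NA_real_, labels = labels)
  for (h in cuts) {
    cl <- stats::cutree(hc, h = h)
    sizes <- table(cl)
    cand <- as.integer(names(sizes)[sizes >= min_size])
    valid <- integer(0)
    for (m in cand) {
      members <- which(cl == m)
      mean_d <- mean(diss[members, members][upper.tri(diag(length(members)))])
      if (mean_d <= coherence * h) valid <- c(valid, m)
    }
    covered <- sum(sizes[as.character(valid)])
    # prefer more valid branches; on ties, the cut assigning more features
    if (length(valid) > best$count ||
        (length(valid) == best$count && covered >= best$covered)) {
      lab <- integer(n)
      sz <- sizes[as.character(valid)]
      for (j in seq_along(valid)) {
        mod <- valid[order(-sz)][j]
        lab[cl == mod] <- j
      }
      best <- list(count = length(valid), covered = covered, h = h,
                   labels = stats::setNames(lab, rownames(diss)))
    }
  }
  out <- best$labels
  # adaptive per-branch refinement: features merging into a branch just
  # below the global cut (loose stragglers) are split off by recursively
  # cutting the branch sub-dendrogram at its largest internal height gap,
  # keeping the dominant core while it stays above min_size
  for (m in sort(unique(out[out > 0L]))) {
    members <- which(out == m)
    core <- .prune_branch(similarity, members, min_size)
    out[setdiff(members, core)] <- 0L
  }
  # renumber by decreasing size after pruning
  mods <- sort(unique(out[out > 0L]))
  sizes <- vapply(mods, function(m) sum(out == m), integer(1))
  relab <- out
  for (j in seq_along(mods)) relab[out == mods[order(-sizes)][j]] <- j
  attributes(relab) <- attributes(out)
  out <- relab
  attr(out, "cut_height") <- best$h
  attr(out, "dendro") <- hc
  out
}

# Iterated pruning of one branch on mean within-branch similarity. TOM
# flatters weakly connected features (its denominator is the smaller
# connectivity), so pruning works on the direct similarity (the adjacency
# when available): core members share high mutual similarity while
# stragglers that merged just below the global cut connect only weakly.
# Members below `rel_frac` times the branch median mean-similarity are
# dropped and the rule re-applied until stable (or the core would fall
# below min_size). Constant profiles (e.g. exact blocks) are untouched.
.prune_branch <- function(sim, members, min_size, rel_frac = 0.5,
                          max_depth = 20L) {
  for (iter in seq_len(max_depth)) {
    if (length(members) <= min_size) return(members)
    s <- rowMeans(sim[members, members, drop = FALSE])
    thr <- rel_frac * stats::median(s)
    core <- members[s >= thr]
    if (length(core) == length(members)) return(members)
    if (length(core) < min_size) return(members)
    members <- core
  }
  members
}

# First principal component of a standardized module, sign-aligned with the
# module mean profile; unit norm.
.module_eigengene <- function(z_mod) {
  if (nrow(z_mod) == 1L) {
    me <- as.numeric(z_mod[1L, ])
    me <- me / sqrt(sum(me^2))
    return(list(me = me, var_explained = 1))
  }
  sv <- svd(z_mod, nu = 0L, nv = 1L)
  me <- sv$v[, 1L]
  if (stats::cor(me, colMeans(z_mod)) < 0) me <- -me
  list(me = me, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Module eigengenes with correlation-based merging
#'
#' Each module's eigengene is the first principal component of its
#' standardized expression, sign-aligned so it correlates positively with
#' the module mean profile, and scaled to unit norm. Module pairs whose
#' eigengene dissimilarity `1 - cor(ME_a, ME_b)` falls below `merge_cut`
#' are merged iteratively (closest pair first), recomputing eigengenes
#' after every merge. Modules are renumbered by decreasing size.
#'
#' @param x features x samples matrix.
#' @param labels integer module labels (0 = unassigned), e.g. from
#'   [detect_modules()].
#' @param merge_cut eigengene dissimilarity threshold (default 0.25).
#' @return list of class `module_set`: `labels`, `eigengenes` (modules x
#'   samples matrix, rows `ME1`, ...), `var_explained`, `sizes`,
#'   `merge_history` (data.frame of performed merges).
#' @export
eigengenes_and_merge <- function(x, labels, merge_cut = 0.25) {
  stopifnot(length(labels) == nrow(x))
  labels <- as.integer(labels)
  z <- .row_standardize(x)
  history <- data.frame(from = integer(0), into = integer(0),
                        dissimilarity = numeric(0))
  compute_mes <- function(lab) {
    mods <- sort(unique(lab[lab > 0L]))
    mes <- lapply(mods, function(m) .module_eigengene(z[lab == m, , drop = FALSE]))
    list(mods = mods,
         me = do.call(rbind, lapply(mes, `[[`, "me")),
         ve = vapply(mes, `[[`, numeric(1), "var_explained"))
  }
  cur <- compute_mes(labels)
  while (length(cur$mods) > 1L) {
    cm <- stats::cor(t(cur$me))
    diag(cm) <- -Inf
    top <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    d <- 1 - max(cm)
    if (d >= merge_cut) break
    from <- cur$mods[max(top)]
    into <- cur$mods[min(top)]
    labels[labels == from] <- into
    history <- rbind(history,
                     data.frame(from = from, into = into, dissimilarity = d))
    cur <- compute_mes(labels)
  }
  # renumber by decreasing size
  mods <- cur$mods
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new_id <- stats::setNames(rank(-sizes, ties.method = "first"), mods)
  relab <- labels
  for (m in mods) relab[labels == m] <- new_id[as.character(m)]
  cur <- compute_mes(relab)
  me <- cur$me
  if (!is.null(me)) {
    rownames(me) <- paste0("ME", cur$mods)
    colnames(me) <- colnames(x)
  }
  structure(list(
    labels = stats::setNames(relab, rownames(x)),
    eigengenes = me,
    var_explained = stats::setNames(cur$ve, paste0("ME", cur$mods)),
    sizes = stats::setNames(vapply(cur$mods, function(m) sum(relab == m),
                                   integer(1)), paste0("ME", cur$mods)),
    merge_history = history
  ), class = "module_set")
}

#' Module-trait correlation statistics
#'
#' Pearson correlation between each module eigengene and a numeric trait
#' (conventionally control = 0, mutant = 1), with the two-sided p-value from
#' the t-distribution with n - 2 degrees of freedom.
#'
#' @param module_set a [eigengenes_and_merge()] result.
#' @param trait numeric trait vector, one value per sample.
#' @return data.frame: module, size, r, p.
#' @export
module_trait_stats <- function(module_set, trait) {
  me <- module_set$eigengenes
  stopifnot(ncol(me) == length(trait))
  n <- length(trait)
  if (stats::sd(trait) == 0) {
    warning("trait is constant; correlations undefined")
    return(data.frame(module = rownames(me), size = as.integer(module_set$sizes),
                      r = NA_real_, p = NA_real_))
  }
  r <- apply(me, 1L, function(v) stats::cor(v, trait))
  p <- if (n < 4L) {
    rep(NA_real_, length(r))
  } else {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  data.frame(module = rownames(me), size = as.integer(module_set$sizes),
             r = r, p = p, row.names = NULL)
}

#' Module membership, peptide significance and hub features
#'
#' MM is the correlation of each feature with its own module's eigengene;
#' PS is the signed correlation of the feature with the trait. Hubs are
#' assigned features with `MM >= mm_cut` and `|PS| >= ps_cut`, ranked by
#' `MM * |PS|` descending (ties by feature id). Unassigned features have
#' `MM = NA` and are never hubs.
#'
#' @param x features x samples matrix.
#' @param module_set a [eigengenes_and_merge()] result.
#' @param trait numeric trait vector.
#' @param mm_cut,ps_cut hub thresholds (defaults 0.8 and 0.5).
#' @return data.frame: feature_id, module, mm, ps, hub; sorted in input
#'   feature order, with the ranked hub ids in attribute `hubs`.
#' @export
membership_significance_hubs <- function(x, module_set, trait,
                                         mm_cut = 0.8, ps_cut = 0.5) {
  labels <- module_set$labels
  me <- module_set$eigengenes
  mm <- rep(NA_real_, nrow(x))
  for (m in sort(unique(labels[labels > 0L]))) {
    rows <- which(labels == m)
    mm[rows] <- as.vector(stats::cor(t(x[rows, , drop = FALSE]),
                                     me[paste0("ME", m), ]))
  }
  ps <- as.vector(stats::cor(t(x), trait))
  hub <- !is.na(mm) & mm >= mm_cut & abs(ps) >= ps_cut
  out <- data.frame(feature_id = rownames(x), module = as.integer(labels),
                    mm = mm, ps = ps, hub = hub,
                    stringsAsFactors = FALSE, row.names = NULL)
  ranked <- out[out$hub, ]
  ranked <- ranked[order(-(ranked$mm * abs(ranked$ps)), ranked$feature_id), ]
  attr(out, "hubs") <- ranked$feature_id
  out
}

#' Build a signed co-expression module set end-to-end
#'
#' Filters features with excessive missingness (> `max_missing`), picks the
#' soft-threshold power, builds the signed adjacency and TOM, detects
#' modules on the TOM dendrogram, merges close eigengenes and computes
#' module-trait and per-feature MM/PS statistics.
#'
#' @param x features x samples log2 matrix.
#' @param trait numeric trait vector (control = 0, mutant = 1).
#' @param powers,r2_target,max_mean_k passed to [pick_soft_threshold()].
#' @param min_size,merge_cut,mm_cut,ps_cut tuning parameters of the module
#'   and hub steps.
#' @param max_missing maximum tolerated per-feature missing fraction.
#' @return list of class `comodules_result` with `scan`, `power`, `modules`
#'   (a `module_set`), `trait_stats`, `membership`, `params`.
#' @export
build_coexpression <- function(x, trait, powers = 1:20, r2_target = 0.85,
                               max_mean_k = 100, min_size = 50L,
                               merge_cut = 0.25, mm_cut = 0.8, ps_cut = 0.5,
                               max_missing = 0.2) {
  miss <- rowMeans(is.na(x))
  v <- apply(x, 1L, stats::var, na.rm = TRUE)
  keep <- miss <= max_missing & is.finite(v) & v > 0
  if (any(!keep)) {
    message(sum(!keep), " feature(s) excluded from network construction ",
            "(missingness or zero variance)")
  }
  x <- x[keep, , drop = FALSE]
  scan <- pick_soft_threshold(x, powers, r2_target, max_mean_k)
  adj <- signed_adjacency(x, scan$power)
  tom <- tom_similarity(adj)
  labels <- detect_modules(1 - tom, min_size = min_size, similarity = adj)
  ms <- eigengenes_and_merge(x, labels, merge_cut = merge_cut)
  structure(list(
    scan = scan, power = scan$power, modules = ms,
    trait_stats = module_trait_stats(ms, trait),
    membership = membership_significance_hubs(x, ms, trait, mm_cut, ps_cut),
    params = list(min_size = min_size, merge_cut = merge_cut,
                  mm_cut = mm_cut, ps_cut = ps_cut,
                  max_missing = max_missing, cut_height = attr(labels, "cut_height"))
  ), class = "comodules_result")
}
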