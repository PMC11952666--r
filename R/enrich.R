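#' Read a GMT gene-set file
#'
#' Standard tab-delimited format: set name, description, then member ids.
#' Empty sets are dropped with a warning; duplicate members within a set are
#' removed.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "",
                 character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- names_
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty set(s) dropped: ",
            paste(names_[empty], collapse = ", "))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  attr(sets, "description") <- stats::setNames(desc, names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named descriptions (default `"NA"`).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("NA", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Hypergeometric over-representation analysis
#'
#' For every set, the overlap k between the query and the set (both
#' restricted to the universe) is tested with the hypergeometric upper tail
#' `P(X >= k)`; BH adjustment across sets. Results are sorted by p ascending
#' (ties by term name). Query ids outside the universe are dropped with a
#' message.
#'
#' @param query character vector of feature ids of interest.
#' @param collection named list of sets (e.g. from [read_gmt()]).
#' @param universe character vector of all scorable ids.
#' @param p_cut,q_cut cutoffs recorded for the `significant` column
#'   (defaults 0.05 / 0.05).
#' @return data.frame: term, k, K, n, N, p, q, significant.
#' @export
ora_test <- function(query, collection, universe, p_cut = 0.05,
                     q_cut = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query id(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  if (n == 0L) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  }
  res <- do.call(rbind, lapply(names(collection), function(term) {
    set <- intersect(unique(collection[[term]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res$significant <- res$p < p_cut & res$q < q_cut
  res[order(res$p, res$term), , drop = FALSE]
}

# Running-sum enrichment score of one set within a ranked list.
.es_score <- function(in_set, weights) {
  n <- length(in_set)
  w_hit <- weights * in_set
  sum_hit <- sum(w_hit)
  if (sum_hit == 0) sum_hit <- 1
  n_miss <- n - sum(in_set)
  step <- w_hit / sum_hit - (!in_set) / n_miss
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Gene-set enrichment by weighted running sum
#'
#' Features are ranked by a signed score (descending); the enrichment score
#' of a set is the signed maximum deviation of the weighted
#' Kolmogorov-Smirnov running sum (hit weight proportional to
#' `|score|^weight`). The null distribution comes from gene-label
#' permutations (random sets of the same size); NES is the ES divided by the
#' mean |null ES| of the same sign, and the permutation p-value is the
#' frequency of same-sign nulls at least as extreme (with the +1
#' continuity correction). BH adjustment across sets.
#'
#' @param scores named numeric vector (feature ids -> ranking score).
#' @param collection named list of sets.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after intersecting with the
#'   ranked list (defaults 10 and 500); undersized sets are skipped with a
#'   message.
#' @param weight running-sum weight exponent (default 1).
#' @return data.frame: term, size, es, nes, p, q.
#' @export
gsea_score <- function(scores, collection, n_perm = 1000L, seed = 1L,
                       min_size = 10L, max_size = 500L, weight = 1) {
  if (any(!is.finite(scores))) stop("ranking scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  ids <- names(scores)
  w <- abs(scores)^weight
  set.seed(seed)
  res <- list()
  for (term in names(collection)) {
    members <- intersect(collection[[term]], ids)
    size <- length(members)
    if (size < min_size || size > max_size) {
      message("set ", term, " skipped (size ", size, " outside bounds)")
      next
    }
    in_set <- ids %in% members
    es <- .es_score(in_set, w)
    null_es <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(length(ids), size)
      flag <- logical(length(ids))
      flag[idx] <- TRUE
      .es_score(flag, w)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    res[[term]] <- data.frame(term = term, size = size, es = es, nes = nes,
                              p = p, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(term = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      q = numeric(0)))
  }
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[order(out$p, out$term), , drop = FALSE]
}

#' PCA-based sample outlier screen
#'
#' Samples are projected on the first two principal components of the
#' standardized feature matrix; within each group (>= 3 samples) a sample is
#' flagged when its distance from the group centroid (component-wise median,
#' so the centroid is not dragged by the outlier under test) exceeds `k_sd`
#' times the median within-group centroid distance. Flags are reported only -
#' removing flagged samples is the caller's decision.
#'
#' @param x features x samples matrix.
#' @param groups group label per sample.
#' @param k_sd flagging multiple (default 3).
#' @return data.frame: sample, group, pc1, pc2, dist, flagged.
#' @export
pca_outlier_screen <- function(x, groups, k_sd = 3) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(x))
  keep <- apply(x, 1L, function(r) stats::sd(r, na.rm = TRUE) > 0)
  if (any(keep)) {
    z <- .row_standardize(x[keep, , drop = FALSE])
    z[is.na(z)] <- 0
    pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    proj <- pc$x[, seq_len(k), drop = FALSE]
  } else {
    proj <- matrix(0, ncol(x), 2L)  # no variable features: all coincide
  }
  k <- ncol(proj)
  out <- data.frame(sample = colnames(x), group = as.character(groups),
                    pc1 = proj[, 1L],
                    pc2 = if (k >= 2L) proj[, 2L] else 0,
                    dist = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3L) {
      warning("group ", g, " has fewer than 3 samples; skipped")
      next
    }
    # component-wise median centroid: robust to the outlier being tested
    centroid <- apply(proj[idx, , drop = FALSE], 2L, stats::median)
    d <- sqrt(rowSums(sweep(proj[idx, , drop = FALSE], 2L, centroid)^2))
    out$dist[idx] <- d
    med <- stats::median(d)
    out$flagged[idx] <- med > 0 & d > k_sd * med
  }
  out
}
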