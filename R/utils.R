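#' @keywords internal
"_PACKAGE"

# Shared amino-acid alphabet for motif work (20 canonical residues).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

WINDOW_WIDTH <- 15L
WINDOW_CENTER <- 8L

#' Area under the ROC curve from scores and binary labels
#'
#' Rank-based (Mann-Whitney) AUROC with ties handled by midranks. Used to
#' quantify how well a continuous score separates a labelled positive class
#' (e.g. true kinase substrates) from the rest.
#'
#' @param score numeric vector of scores, larger = more positive-like.
#' @param label logical or 0/1 vector, same length as `score`.
#' @return a single number in \[0, 1\]; 0.5 means no separation.
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label))
  keep <- is.finite(score) & !is.na(label)
  score <- score[keep]
  label <- label[keep]
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auroc() needs at least one positive and one negative label")
  }
  r <- rank(score)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Standardize the rows of a matrix to mean 0, sd 1 across columns.
# Zero-variance rows become all-zero rather than NaN.
.row_standardize <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1L, stats::sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- 1
  sweep(sweep(x, 1L, mu, "-"), 1L, s, "/")
}

# Deterministic seed derivation: stage offsets keep sub-streams distinct
# while staying within 32-bit integer range.
.stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * offset) %% .Machine$integer.max)
}

.assert_two_groups <- function(groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    stop("exactly two groups are required, got ", nlevels(groups))
  }
  groups
}
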