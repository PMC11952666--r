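#' Write a feature-by-sample intensity matrix as TSV
#'
#' First column `feature_id`, remaining columns samples. Deterministic
#' formatting (15 significant digits, no quoting) so identical inputs give
#' byte-identical files.
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @export
write_intensity_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x),
                   signif(x, 15), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an intensity TSV written by [write_intensity_tsv()]
#'
#' @param path file path.
#' @return numeric matrix with feature ids as row names.
#' @export
read_intensity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a data.frame as TSV (deterministic formatting)
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write kinase PSSMs as a long-format TSV
#'
#' Columns: kinase, position (1-15), then the 20 residue probabilities.
#'
#' @param kinase_models named list of PSSM matrices.
#' @param path output path.
#' @export
write_pssm_tsv <- function(kinase_models, path) {
  rows <- do.call(rbind, lapply(names(kinase_models), function(k) {
    p <- kinase_models[[k]]
    data.frame(kinase = k, position = seq_len(nrow(p)), p,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  write_tsv(rows, path)
}

#' Read kinase PSSMs from a long-format TSV
#'
#' @param path file written by [write_pssm_tsv()].
#' @return named list of 15 x 20 PSSM matrices.
#' @export
read_pssm_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  aa_cols <- setdiff(names(df), c("kinase", "position"))
  lapply(split(df, df$kinase), function(d) {
    d <- d[order(d$position), ]
    m <- as.matrix(d[, aa_cols])
    rownames(m) <- paste0("pos", d$position)
    m
  })
}

#' Write a provenance sidecar for an output file
#'
#' Records everything needed to regenerate the file: the generating
#' function, its parameters, seeds, package version and md5 checksums of
#' the input files. Written as `<path>.prov.json`.
#'
#' @param path path of the output file the sidecar describes.
#' @param stage name of the producing pipeline stage.
#' @param params list of parameters (must be JSON-serializable).
#' @param inputs character vector of input file paths (md5-summed).
#' @return the sidecar path, invisibly.
#' @export
write_provenance <- function(path, stage, params, inputs = character(0)) {
  sidecar <- paste0(path, ".prov.json")
  record <- list(
    file = basename(path),
    stage = stage,
    package = "phosflow",
    version = as.character(utils::packageVersion("phosflow")),
    params = params,
    input_md5 = if (length(inputs)) {
      as.list(stats::setNames(unname(tools::md5sum(inputs)),
                              basename(inputs)))
    } else NULL
  )
  jsonlite::write_json(record, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(sidecar)
}
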