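#' Read and write pipeline tables
#'
#' TSV conventions used throughout: count and fold-change matrices are
#' written features-in-rows with the first column `feature_id`; metadata
#' is one row per sample; normalization factors are one row per sample
#' with `sample_id`, `lib_size`, `tmm_factor`.
#'
#' @param m numeric/integer matrix with feature row names and sample
#'   column names.
#' @param path file path.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @name radmir-io
NULL

#' @rdname radmir-io
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname radmir-io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname radmir-io
#' @param meta sample metadata data frame (`sample_id`, `animal_id`,
#'   `dose_gy`, `timepoint`, `day`, `sex`, `survived`).
#' @export
write_metadata_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname radmir-io
#' @export
read_metadata_tsv <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  meta$survived <- as.logical(meta$survived)
  meta
}

#' @rdname radmir-io
#' @param factors a `norm_factors` object from [tmm_factors()].
#' @export
write_norm_factors_tsv <- function(factors, path) {
  df <- data.frame(sample_id = names(factors$factor),
                   lib_size = factors$lib_size,
                   tmm_factor = factors$factor)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname radmir-io
#' @param truth a [planted_truth()].
#' @export
write_planted_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
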