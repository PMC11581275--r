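#' Prefilter sparsely detected features
#'
#' Removes miRNAs detected (count > 0) in fewer than `min_nonzero_frac`
#' of samples. The boundary is inclusive on the keep side: a feature
#' non-zero in exactly 40% of samples is retained under the default
#' threshold. Feature order is preserved and the operation is idempotent.
#'
#' @param counts integer count matrix, features x samples.
#' @param min_nonzero_frac minimum fraction of samples with a non-zero
#'   count, in (0, 1\].
#' @return the filtered count matrix.
#' @export
prefilter_features <- function(counts, min_nonzero_frac = 0.40) {
  stopifnot(is.matrix(counts), min_nonzero_frac > 0, min_nonzero_frac <= 1)
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    warning("empty count matrix; nothing to filter")
    return(counts)
  }
  frac <- rowMeans(counts > 0)
  counts[frac >= min_nonzero_frac, , drop = FALSE]
}

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values normalization factors: the reference sample is
#' the one whose upper quartile is closest to the mean upper quartile;
#' each sample's factor is the precision-weighted mean of gene-wise
#' log-ratios (M-values) against the reference after trimming the most
#' extreme `trim_M` of M-values and `trim_A` of average abundances; the
#' factor vector is rescaled to geometric mean 1. Computation is
#' delegated to the canonical implementation in edgeR.
#'
#' @param counts integer count matrix, features x samples (>= 2 samples,
#'   all library sizes positive).
#' @param trim_M,trim_A two-sided trim fractions for the M and A values
#'   (defaults 0.30 and 0.05).
#' @return object of class `norm_factors`: list with `factor` (named,
#'   geometric mean 1) and `lib_size` (named column sums).
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have a positive library size")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  structure(list(factor = setNames(as.numeric(f), colnames(counts)),
                 lib_size = setNames(as.numeric(lib), colnames(counts))),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("TMM normalization factors for", length(x$factor), "samples",
      sprintf("(range %.3f-%.3f)\n", min(x$factor), max(x$factor)))
  invisible(x)
}

#' Counts per million
#'
#' `cpm[i, j] = counts[i, j] / (lib_size[j] * factor[j]) * 1e6`.
#'
#' @param counts integer count matrix, features x samples.
#' @param factors a `norm_factors` object aligned with `counts`; `NULL`
#'   uses unit factors (plain library-size CPM).
#' @return numeric CPM matrix with the dimensions of `counts`.
#' @export
cpm_matrix <- function(counts, factors = NULL) {
  stopifnot(is.matrix(counts))
  lib <- colSums(counts)
  f <- rep(1, ncol(counts))
  if (!is.null(factors)) {
    stopifnot(inherits(factors, "norm_factors"))
    if (!identical(names(factors$factor), colnames(counts))) {
      stop("normalization factors are not aligned with the count matrix samples")
    }
    lib <- factors$lib_size
    f <- factors$factor
  }
  sweep(counts, 2, lib * f, "/") * 1e6
}

#' Per-animal log2 fold change against the pre-irradiation baseline
#'
#' For every post-irradiation sample, computes
#' `log2((cpm_post + pseudocount) / (cpm_pre + pseudocount))` against the
#' same animal's pre-irradiation sample. Animals without exactly one
#' baseline sample are excluded with a message. The pseudocount keeps all
#' values finite; a feature at zero in both samples maps to exactly 0.
#'
#' @param cpm CPM matrix, features x samples.
#' @param meta sample metadata (needs `sample_id`, `animal_id`,
#'   `timepoint`).
#' @param pseudocount added to both numerator and denominator (default 1).
#' @param baseline timepoint label of the pre-irradiation sample.
#' @return object of class `fold_change`: list with `fc` (features x
#'   post-irradiation samples) and `meta` (metadata rows for those
#'   columns).
#' @export
log2fc_baseline <- function(cpm, meta, pseudocount = 1.0, baseline = "pre") {
  stopifnot(is.matrix(cpm), all(colnames(cpm) %in% meta$sample_id))
  meta <- meta[match(colnames(cpm), meta$sample_id), ]
  keep_animals <- character(0)
  for (a in unique(meta$animal_id)) {
    n_base <- sum(meta$animal_id == a & meta$timepoint == baseline)
    if (n_base == 1L) keep_animals <- c(keep_animals, a)
  }
  dropped <- setdiff(unique(meta$animal_id), keep_animals)
  if (length(dropped)) {
    message("excluding ", length(dropped),
            " animal(s) without exactly one baseline sample: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(keep_animals)) stop("no animal has a pre-irradiation baseline sample")

  post <- meta$animal_id %in% keep_animals & meta$timepoint != baseline
  # animal -> its baseline sample id
  base_of <- setNames(meta$sample_id[meta$timepoint == baseline],
                      meta$animal_id[meta$timepoint == baseline])
  base_col <- base_of[meta$animal_id[post]]
  fc <- log2((cpm[, post, drop = FALSE] + pseudocount) /
             (cpm[, base_col, drop = FALSE] + pseudocount))
  colnames(fc) <- meta$sample_id[post]
  structure(list(fc = fc, meta = meta[post, , drop = FALSE]),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat("log2 fold-change matrix:", nrow(x$fc), "features x", ncol(x$fc),
      "post-irradiation samples\n")
  invisible(x)
}
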