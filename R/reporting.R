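#' Principal component report of a fold-change matrix
#'
#' Centered PCA of the samples (columns); explained-variance fractions
#' sum to one over all components.
#'
#' @param fc a `fold_change` object or plain matrix (features x samples).
#' @return list of class `pca_report`: `scores` (samples x components),
#'   `explained` (fractions), `sdev`.
#' @export
pca_report <- function(fc) {
  m <- if (inherits(fc, "fold_change")) fc$fc else fc
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L || ncol(m) < 2L) stop("PCA needs at least 2 features and 2 samples")
  if (all(apply(m, 1, var) == 0)) stop("constant matrix: PCA undefined")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, explained = explained, sdev = pc$sdev),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  e2 <- if (length(x$explained) > 1L) x$explained[2] else 0
  cat("PCA:", nrow(x$scores), "samples;",
      sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$explained[1], 100 * e2))
  invisible(x)
}

#' Hierarchical clustering report
#'
#' Euclidean-distance agglomerative clustering (average linkage) of the
#' samples over a feature subset, as used for marker heat maps. Returns
#' the tree, leaf order and the subset matrix in leaf order.
#'
#' @param fc a `fold_change` object or matrix.
#' @param subset non-empty feature subset to cluster on (default all
#'   features).
#' @param linkage agglomeration method (default `"average"`).
#' @return list of class `hclust_report`: `hclust` (or `NULL` for a
#'   single sample), `order` (sample IDs in leaf order), `heights`,
#'   `matrix` (features x ordered samples).
#' @export
hclust_report <- function(fc, subset = NULL, linkage = "average") {
  m <- if (inherits(fc, "fold_change")) fc$fc else fc
  subset <- subset %||% rownames(m)
  if (!length(subset)) stop("feature subset must be non-empty")
  missing <- setdiff(subset, rownames(m))
  if (length(missing)) stop("features not in matrix: ", paste(missing, collapse = ", "))
  m <- m[subset, , drop = FALSE]
  if (ncol(m) == 1L) {
    return(structure(list(hclust = NULL, order = colnames(m),
                          heights = numeric(0), matrix = m),
                     class = "hclust_report"))
  }
  d <- dist(t(m), method = "euclidean")
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, order = colnames(m)[hc$order],
                 heights = hc$height, matrix = m[, hc$order, drop = FALSE]),
            class = "hclust_report")
}

#' @export
print.hclust_report <- function(x, ...) {
  cat("Hierarchical clustering (Euclidean,",
      if (is.null(x$hclust)) "trivial tree" else x$hclust$method,
      "):", length(x$order), "samples,", nrow(x$matrix), "features\n")
  invisible(x)
}
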