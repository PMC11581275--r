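#' Dose- and time-response marker regression
#'
#' Fits an ordinary least squares line to a feature's log2 fold change
#' against numeric radiation dose (Gy) or days since irradiation, and
#' tests whether the slope deviates from zero (F test; F equals the
#' squared slope t statistic). By default the regression points are
#' per-dose (or per-timepoint) means of the stratum, pooled over the
#' other axis -- the convention that matches the small residual degrees
#' of freedom of published marker fits -- with a per-animal-point variant
#' available.
#'
#' For the time axis the pre-irradiation baseline (day 0, fold change 0
#' by construction) is included as a regression point by default; for the
#' dose axis no (0 Gy, 0) origin is added by default. Both choices are
#' arguments.
#'
#' @param fc a `fold_change` object (or matrix plus `meta`).
#' @param meta metadata for the fold-change columns.
#' @param feature feature ID (row of the fold-change matrix).
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @param points `"means"` (default) regresses stratum means per axis
#'   level; `"animals"` regresses every sample value.
#' @param include_origin add a (0, 0) point: default `FALSE` for dose,
#'   `TRUE` (the day-0 baseline) for time.
#' @return object of class `marker_fit`: `feature`, `axis`, `stratum`,
#'   `slope`, `F`, `p`, `n_points`.
#' @export
dose_response_fit <- function(fc, meta = NULL, feature, stratum = "all",
                              points = c("means", "animals"),
                              include_origin = FALSE) {
  axis_response_fit(fc, meta, feature, stratum, match.arg(points),
                    include_origin, axis = "dose")
}

#' @rdname dose_response_fit
#' @export
time_response_fit <- function(fc, meta = NULL, feature, stratum = "all",
                              points = c("means", "animals"),
                              include_origin = TRUE) {
  axis_response_fit(fc, meta, feature, stratum, match.arg(points),
                    include_origin, axis = "time")
}

axis_response_fit <- function(fc, meta, feature, stratum, points,
                              include_origin, axis) {
  if (inherits(fc, "fold_change")) {
    meta <- meta %||% fc$meta
    fc <- fc$fc
  }
  stopifnot(feature %in% rownames(fc))
  meta <- meta[match(colnames(fc), meta$sample_id), ]
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(meta)),
                 male = meta$sex == "M",
                 female = meta$sex == "F",
                 stop("stratum must be 'all', 'male' or 'female'"))
  y <- fc[feature, keep]
  x <- if (axis == "dose") meta$dose_gy[keep] else meta$day[keep]
  if (points == "means") {
    agg <- tapply(y, x, mean)
    x <- as.numeric(names(agg))
    y <- as.numeric(agg)
  }
  if (include_origin) {
    x <- c(0, x)
    y <- c(0, y)
  }
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct ", axis, " levels with data in stratum '",
         stratum, "'")
  }
  if (var(y) == 0) {
    fitv <- list(slope = 0, F = 0, p = 1)
  } else {
    fit <- lm(y ~ x)
    rss <- sum(fit$residuals^2)
    if (rss <= 1e-12 * sum((y - mean(y))^2)) {
      # numerically exact linear response: the slope test saturates
      fitv <- list(slope = unname(coef(fit)["x"]), F = Inf, p = 0)
    } else {
      sm <- summary(fit)
      tval <- sm$coefficients["x", "t value"]
      Fv <- tval^2
      p <- pf(Fv, 1, fit$df.residual, lower.tail = FALSE)
      fitv <- list(slope = unname(coef(fit)["x"]), F = unname(Fv), p = unname(p))
    }
  }
  structure(
    list(feature = feature, axis = axis, stratum = stratum,
         slope = fitv$slope, F = fitv$F, p = fitv$p, n_points = length(x)),
    class = "marker_fit"
  )
}

#' @export
print.marker_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s [%s]: slope %.3f per %s, F = %.2f, p = %.3g (%d points)\n",
              x$feature, x$axis, x$stratum, x$slope,
              if (x$axis == "dose") "Gy" else "day", x$F, x$p, x$n_points))
  invisible(x)
}

#' Classify a marker's sex dependence
#'
#' Given the pooled, male and female regression fits of one feature,
#' labels it `sex-independent` when the pooled slope is significant,
#' `male-specific` (resp. `female-specific`) when significant in exactly
#' one sex stratum, and `none` otherwise. Pooled significance does not
#' mask a sex-exclusive pattern: a marker significant both pooled and in
#' a single sex carries both labels.
#'
#' @param fit_all,fit_male,fit_female `marker_fit` objects for the three
#'   strata.
#' @param alpha significance level.
#' @return character vector of labels (one or two of `sex-independent`,
#'   `male-specific`, `female-specific`, or `none`).
#' @export
classify_marker <- function(fit_all, fit_male, fit_female, alpha = 0.05) {
  sig <- function(f) !is.na(f$p) && f$p < alpha
  labels <- character(0)
  if (sig(fit_all)) labels <- "sex-independent"
  if (sig(fit_male) && !sig(fit_female)) labels <- c(labels, "male-specific")
  if (sig(fit_female) && !sig(fit_male)) labels <- c(labels, "female-specific")
  if (!length(labels)) labels <- "none"
  labels
}

#' Screen all features along one axis
#'
#' Convenience wrapper running [dose_response_fit()] or
#' [time_response_fit()] for every feature in all three sex strata and
#' assembling the marker table.
#'
#' @param fc a `fold_change` object.
#' @param axis `"dose"` or `"time"`.
#' @param alpha significance level for the labels.
#' @param ... passed to the per-feature fit.
#' @return data frame: `feature`, `axis`, `stratum`, `slope`, `F`, `p`,
#'   `n_points`, `label` (comma-joined classification, on the `all`
#'   rows).
#' @export
screen_markers <- function(fc, axis = c("dose", "time"), alpha = 0.05, ...) {
  axis <- match.arg(axis)
  fitfun <- if (axis == "dose") dose_response_fit else time_response_fit
  rows <- list()
  for (f in rownames(fc$fc)) {
    fits <- lapply(c(all = "all", male = "male", female = "female"),
                   function(s) fitfun(fc, feature = f, stratum = s, ...))
    label <- paste(classify_marker(fits$all, fits$male, fits$female, alpha),
                   collapse = ",")
    for (s in names(fits)) {
      ft <- fits[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, axis = axis, stratum = s, slope = ft$slope, F = ft$F,
        p = ft$p, n_points = ft$n_points,
        label = if (s == "all") label else NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-marker ROC with bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with midranks for ties,
#' plus a stratified percentile bootstrap confidence interval.
#'
#' @param values numeric marker values (e.g. normalized expression).
#' @param positive logical, `TRUE` for the positive class (e.g.
#'   irradiated samples vs pre-irradiation baseline).
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list of class `roc_summary`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `n_boot`.
#' @export
single_marker_auc <- function(values, positive, n_boot = 2000L,
                              conf = 0.95, seed = NULL) {
  positive <- as.logical(positive)
  stopifnot(length(values) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("both a positive and a negative class are required for a ROC curve")
  }
  restore <- set_local_seed(seed)
  on.exit(restore())
  auc <- rank_auc(values, positive)
  pos_idx <- which(positive)
  neg_idx <- which(!positive)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- c(pos_idx[sample.int(n1, n1, replace = TRUE)],
             neg_idx[sample.int(n0, n0, replace = TRUE)])
    rank_auc(values[idx], positive[idx])
  }, numeric(1))
  q <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(auc = auc, ci_low = q[1], ci_high = q[2],
                 n_pos = n1, n_neg = n0, n_boot = n_boot),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d pos / %d neg, %d bootstrap)\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg, x$n_boot))
  invisible(x)
}
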