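#' Four-way factorial ANOVA per feature
#'
#' Screens every feature's log2 fold change across the four study
#' factors -- radiation dose (RD, categorical), time since irradiation
#' (TSI, categorical post-irradiation timepoints), Sex, and survival
#' outcome (RRiF) -- reporting an F test, p-value and classical eta
#' squared (term SS / total SS) for each of the 15 main-effect and
#' interaction terms of the full factorial.
#'
#' Because every animal contributes one fold-change value per
#' post-irradiation timepoint against its own single baseline sample,
#' the values of one animal are correlated (they share the baseline).
#' The screen therefore uses the classical split-plot error structure:
#' terms constant within an animal (RD, Sex, RRiF and their mutual
#' interactions) are tested on the per-animal means against the
#' animal-stratum error, which absorbs the shared baseline noise, while
#' TSI-containing terms are tested against the within-animal residual in
#' which the baseline cancels. Within each stratum, sums of squares are
#' Type II (each term against the model holding every term that does not
#' contain it), which is order-invariant and appropriate for this
#' unbalanced design (unequal sex ratios, survival partially confounded
#' with dose).
#'
#' Rank deficiency is handled by pivoted QR; a term whose design columns
#' add no rank (fully aliased, e.g. a high-order interaction with empty
#' cells) is flagged `estimable = FALSE` and carries `NA` statistics
#' rather than numbers.
#'
#' @param fc a `fold_change` object from [log2fc_baseline()], or a plain
#'   matrix (then `meta` must cover its columns).
#' @param meta metadata for the fold-change columns; defaults to the
#'   metadata embedded in `fc`.
#' @param alpha significance level recorded alongside the results (used
#'   downstream by [curate_de_union()]).
#' @return data frame of class `anova_screen` with columns `feature`,
#'   `term`, `stratum` (`"between"`/`"within"`), `df`, `ss`, `F`, `p`,
#'   `eta_sq`, `estimable`; attributes `ss_total`, `ss_resid_between`,
#'   `ss_resid_within` (named per feature), `df_resid_between`,
#'   `df_resid_within` and `alpha`. Sums of squares are on the scale of
#'   the full sample layout, so term and residual SS add up to the total
#'   SS when the design is balanced and fully estimable.
#' @export
fit_four_way_anova <- function(fc, meta = NULL, alpha = 0.05) {
  if (inherits(fc, "fold_change")) {
    meta <- meta %||% fc$meta
    fc <- fc$fc
  }
  stopifnot(is.matrix(fc), !is.null(meta))
  meta <- meta[match(colnames(fc), meta$sample_id), ]
  fac <- data.frame(
    RD = factor(meta$dose_gy),
    TSI = droplevels(factor(meta$timepoint)),
    Sex = factor(meta$sex),
    RRiF = factor(meta$survived, levels = c(FALSE, TRUE)),
    animal = factor(meta$animal_id)
  )
  single <- vapply(fac[c("RD", "TSI", "Sex", "RRiF")],
                   function(f) nlevels(droplevels(f)) < 2L, logical(1))
  for (nm in names(single)[single]) fac[[nm]] <- rep(0, nrow(fac))
  labels15 <- attr(terms(~ RD * TSI * Sex * RRiF), "term.labels")

  Y <- t(fc)  # samples x features
  n <- nrow(Y)
  ss_total <- colSums(scale(Y, scale = FALSE)^2)

  # ---- between-animal stratum: per-animal means ---------------------------
  animals <- levels(fac$animal)
  m_per <- as.integer(table(fac$animal)[animals])
  m <- mean(m_per)  # samples per animal; exact scaling when balanced
  Yb <- rowsum(Y, fac$animal) / m_per
  Yb <- Yb[animals, , drop = FALSE]
  first <- match(animals, fac$animal)
  bfac <- fac[first, c("RD", "Sex", "RRiF"), drop = FALSE]
  bet <- stratum_type2(~ RD * Sex * RRiF, bfac, Yb, single)
  # scale mean-level SS to the full layout so eta^2 shares one denominator
  bet$ss <- lapply(bet$ss, function(s) s * m)
  bet$rss_full <- bet$rss_full * m

  # ---- within-animal stratum: animal intercepts + TSI-containing terms ---
  wit <- within_type2(fac, Y, labels15, single)

  rows <- list()
  between_labels <- c(names(bet$ss), bet$inestimable)
  for (lab in labels15) {
    is_between <- lab %in% between_labels
    src <- if (is_between) bet else wit
    stratum <- if (is_between) "between" else "within"
    if (lab %in% src$inestimable) {
      rows[[lab]] <- data.frame(feature = colnames(Y), term = lab,
                                stratum = stratum, df = NA_integer_,
                                ss = NA_real_, F = NA_real_, p = NA_real_,
                                eta_sq = NA_real_, estimable = FALSE)
      next
    }
    ss <- src$ss[[lab]]
    df1 <- src$df[[lab]]
    Fv <- (ss / df1) / (src$rss_full / src$df_resid)
    p <- pf(Fv, df1, src$df_resid, lower.tail = FALSE)
    eta <- ifelse(ss_total > 0, ss / ss_total, 0)
    Fv[ss_total == 0] <- 0
    p[ss_total == 0] <- 1
    rows[[lab]] <- data.frame(feature = colnames(Y), term = lab,
                              stratum = stratum, df = df1, ss = ss, F = Fv,
                              p = p, eta_sq = eta, estimable = TRUE)
  }
  res <- do.call(rbind, rows)
  res <- res[order(match(res$feature, colnames(Y)),
                   match(res$term, labels15)), ]
  rownames(res) <- NULL
  attr(res, "ss_total") <- ss_total
  attr(res, "ss_resid_between") <- bet$rss_full
  attr(res, "df_resid_between") <- bet$df_resid
  attr(res, "ss_resid_within") <- wit$rss_full
  attr(res, "df_resid_within") <- wit$df_resid
  attr(res, "alpha") <- alpha
  class(res) <- c("anova_screen", "data.frame")
  res
}

# Type II sums of squares for all terms of `fml` fitted to the rows of Y.
# Returns per-term SS (list of per-feature vectors), df, the full-model
# residual SS and df, and the labels of inestimable terms.
stratum_type2 <- function(fml, data, Y, single_level) {
  tt <- terms(fml)
  labels <- attr(tt, "term.labels")
  fmat <- attr(tt, "factors")  # one-sided formula: no response row
  mm <- model.matrix(fml, data = data)
  asgn <- attr(mm, "assign")
  n <- nrow(Y)

  contains <- function(t_small, t_big) all(fmat[, t_small] <= fmat[, t_big])
  rss <- function(cols) {
    q <- qr(mm[, cols, drop = FALSE])
    list(rss = colSums(qr.resid(q, Y)^2), rank = q$rank)
  }
  full <- rss(seq_along(asgn))

  ss <- list()
  df <- list()
  inest <- character(0)
  for (i in seq_along(labels)) {
    vars <- rownames(fmat)[fmat[, i] > 0]
    if (any(single_level[vars])) {
      inest <- c(inest, labels[i])
      next
    }
    others <- setdiff(
      which(!vapply(seq_along(labels), function(j) contains(i, j), logical(1))),
      i)
    d0 <- rss(which(asgn %in% c(0L, others)))
    d1 <- rss(which(asgn %in% c(0L, others, i)))
    k <- d1$rank - d0$rank
    if (k <= 0L) {
      inest <- c(inest, labels[i])
      next
    }
    ss[[labels[i]]] <- pmax(d0$rss - d1$rss, 0)
    df[[labels[i]]] <- k
  }
  list(ss = ss, df = df, rss_full = full$rss, df_resid = n - full$rank,
       inestimable = inest)
}

# Within-animal stratum: the null space of the animal factor. Every
# TSI-containing term of the 15-term factorial is tested Type II against
# animal intercepts plus the other TSI-containing terms not containing it.
within_type2 <- function(fac, Y, labels15, single_level) {
  fml <- ~ RD * TSI * Sex * RRiF
  tt <- terms(fml)
  labels <- attr(tt, "term.labels")
  fmat <- attr(tt, "factors")  # one-sided formula: no response row
  within_idx <- which(fmat["TSI", ] > 0)
  mm <- model.matrix(fml, data = fac)
  asgn <- attr(mm, "assign")
  A <- model.matrix(~ animal, data = fac)
  n <- nrow(Y)

  contains <- function(t_small, t_big) all(fmat[, t_small] <= fmat[, t_big])
  rss <- function(term_ids) {
    X <- cbind(A, mm[, asgn %in% term_ids, drop = FALSE])
    q <- qr(X)
    list(rss = colSums(qr.resid(q, Y)^2), rank = q$rank)
  }
  full <- rss(within_idx)

  ss <- list()
  df <- list()
  inest <- character(0)
  for (i in within_idx) {
    vars <- rownames(fmat)[fmat[, i] > 0]
    if (any(single_level[vars])) {
      inest <- c(inest, labels[i])
      next
    }
    others <- setdiff(
      within_idx[!vapply(within_idx, function(j) contains(i, j), logical(1))],
      i)
    d0 <- rss(others)
    d1 <- rss(c(others, i))
    k <- d1$rank - d0$rank
    if (k <= 0L) {
      inest <- c(inest, labels[i])
      next
    }
    ss[[labels[i]]] <- pmax(d0$rss - d1$rss, 0)
    df[[labels[i]]] <- k
  }
  list(ss = ss, df = df, rss_full = full$rss, df_resid = n - full$rank,
       inestimable = inest)
}

#' Union of differentially expressed features
#'
#' Pools the features significant (`p < alpha`) in at least one estimable
#' ANOVA term and removes duplicates, reporting per-term counts.
#'
#' @param results an `anova_screen` data frame.
#' @param alpha significance cut-off (default the alpha recorded in
#'   `results`).
#' @return object of class `de_set`: list with `union` (character,
#'   first-appearance order), `per_term` (named list of per-term feature
#'   vectors), `counts` (named integer vector) and `alpha`.
#' @export
curate_de_union <- function(results, alpha = attr(results, "alpha") %||% 0.05) {
  stopifnot(nrow(results) > 0)
  sig <- results[results$estimable & !is.na(results$p) & results$p < alpha, ]
  per_term <- split(sig$feature, factor(sig$term, levels = unique(results$term)))
  structure(
    list(union = unique(sig$feature),
         per_term = per_term,
         counts = vapply(per_term, length, integer(1)),
         alpha = alpha),
    class = "de_set"
  )
}

#' @export
print.de_set <- function(x, ...) {
  cat("DE union:", length(x$union), "features significant in >=1 of",
      length(x$per_term), "terms at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Mean effect size and its coefficient of variation
#'
#' Summarises the classical eta-squared values over all estimable,
#' reported terms: the mean and its coefficient of variation (sd / mean).
#'
#' @param results an `anova_screen` data frame.
#' @return list with `mean_eta_sq`, `cv_eta_sq` and `n_terms`.
#' @export
effect_size_summary <- function(results) {
  eta <- results$eta_sq[results$estimable & !is.na(results$eta_sq)]
  if (!length(eta)) stop("no estimable terms: effect sizes unavailable")
  m <- mean(eta)
  list(mean_eta_sq = m,
       cv_eta_sq = if (length(eta) > 1L && m > 0) sd(eta) / m else 0,
       n_terms = length(eta))
}

#' Monte-Carlo power of the cohort design
#'
#' Estimates the power to detect a dose-linked effect of a given effect
#' size (eta squared) under the cohort layout: responses are simulated on
#' the post-irradiation samples as a linear dose trend plus unit Gaussian
#' noise, with the trend calibrated so the expected (marginal) eta
#' squared of the dose term matches `target_eta2`; power is the fraction
#' of replicates in which the four-way ANOVA rejects the RD term at
#' `alpha`.
#'
#' @param design a [study_design()].
#' @param target_eta2 target effect size in (0, 1).
#' @param alpha test level.
#' @param n_reps Monte-Carlo replicates (>= 100 recommended).
#' @param seed integer seed.
#' @return list of class `power_report`: `alpha`, `target_eta2`,
#'   `mean_eta_sq` and `eta_cv` (realised, across replicates),
#'   `n_samples`, `estimated_power`, `n_reps`, `method`.
#' @export
estimate_power_by_simulation <- function(design, target_eta2, alpha = 0.05,
                                         n_reps = 200L, seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            target_eta2 > 0, target_eta2 < 1, n_reps >= 1)
  restore <- set_local_seed(seed)
  on.exit(restore())

  animals <- animal_table(design)
  post_tp <- design$timepoints[-1]
  meta <- expand.grid(timepoint = post_tp, animal_id = animals$animal_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- merge(meta, animals, by = "animal_id", sort = FALSE)
  meta$day <- as.numeric(design$days[meta$timepoint])
  meta$sample_id <- paste(meta$animal_id, meta$timepoint, sep = "_")
  n <- nrow(meta)

  dose_c <- meta$dose_gy - mean(meta$dose_gy)
  sxx <- sum(dose_c^2)
  b <- sqrt(target_eta2 / (1 - target_eta2) * (n - 1) / sxx)
  Y <- matrix(rnorm(n * n_reps), n, n_reps) + b * dose_c
  rownames(Y) <- meta$sample_id
  colnames(Y) <- sprintf("rep%04d", seq_len(n_reps))
  res <- fit_four_way_anova(t(Y), meta, alpha = alpha)
  rd <- res[res$term == "RD", ]
  structure(
    list(alpha = alpha, target_eta2 = target_eta2,
         mean_eta_sq = mean(rd$eta_sq), eta_cv = sd(rd$eta_sq) / mean(rd$eta_sq),
         n_samples = n, estimated_power = mean(rd$p < alpha),
         n_reps = n_reps, method = "monte-carlo"),
    class = "power_report"
  )
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf(
    "Simulated power: %.3f (target eta^2 = %.3g, alpha = %.3g, %d samples, %d reps)\n",
    x$estimated_power, x$target_eta2, x$alpha, x$n_samples, x$n_reps))
  invisible(x)
}
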