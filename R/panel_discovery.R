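#' Per-animal feature matrix for outcome modelling
#'
#' Collapses the fold-change matrix to one row per animal (mean log2 fold
#' change over that animal's post-irradiation samples) and extracts the
#' binary survival outcome -- the unit of analysis for the panel search.
#'
#' @param fc a `fold_change` object.
#' @param features optional feature subset (e.g. the cnvd set).
#' @return list with `x` (animals x features matrix) and `y` (named
#'   logical survival vector).
#' @export
panel_input_matrix <- function(fc, features = NULL) {
  stopifnot(inherits(fc, "fold_change"))
  m <- fc$fc
  if (!is.null(features)) m <- m[intersect(features, rownames(m)), , drop = FALSE]
  animals <- unique(fc$meta$animal_id)
  x <- matrix(NA_real_, length(animals), nrow(m),
              dimnames = list(animals, rownames(m)))
  for (a in animals) {
    x[a, ] <- rowMeans(m[, fc$meta$animal_id == a, drop = FALSE])
  }
  y <- setNames(fc$meta$survived[match(animals, fc$meta$animal_id)], animals)
  list(x = x, y = y)
}

#' Candidate ranking by repeated random forests
#'
#' Trains `n_reps` random forests on bootstrap resamples of the cohort,
#' records the top `panel_size` features by impurity importance in each
#' repetition, and ranks features by their selection frequency. The
#' distinct per-repetition top sets, ordered by the summed frequency of
#' their members, are emitted as seed panels for subpanel enumeration.
#'
#' @param x feature matrix, samples x features.
#' @param y binary outcome (logical or two-level factor).
#' @param n_reps number of forest repetitions (study default 2000).
#' @param top_panels number of seed panels to retain (study default 200).
#' @param panel_size features recorded per repetition (= maximal panel
#'   size, 10).
#' @param num_trees trees per forest.
#' @param seed integer seed; forests run single-threaded for exact
#'   reproducibility.
#' @return object of class `candidate_ranking`: `frequency` (named,
#'   selections / n_reps, descending), `panels` (list of character
#'   vectors), `n_reps`.
#' @export
rank_candidates_rf <- function(x, y, n_reps = 2000L, top_panels = 200L,
                               panel_size = 10L, num_trees = 100L,
                               seed = NULL) {
  y <- as.logical(y)
  stopifnot(is.matrix(x) || is.data.frame(x), length(y) == nrow(x),
            n_reps >= 1L)
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  x <- as.data.frame(x)
  restore <- set_local_seed(seed)
  on.exit(restore())

  m <- min(panel_size, ncol(x))
  freq <- setNames(numeric(ncol(x)), colnames(x))
  set_count <- list()
  for (r in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(nrow(x), replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    fit <- ranger::ranger(
      x = x[idx, , drop = FALSE], y = factor(y[idx]),
      num.trees = num_trees, importance = "impurity",
      num.threads = 1L, seed = sample.int(.Machine$integer.max, 1L)
    )
    imp <- sort(fit$variable.importance, decreasing = TRUE)
    top <- names(imp)[seq_len(m)]
    freq[top] <- freq[top] + 1
    key <- paste(sort(top), collapse = "|")
    set_count[[key]] <- (set_count[[key]] %||% 0L) + 1L
  }
  freq <- freq / n_reps
  freq <- freq[order(-freq, names(freq))]
  sets <- strsplit(names(set_count), "|", fixed = TRUE)
  score <- vapply(sets, function(s) sum(freq[s]), numeric(1))
  ord <- order(-score, names(set_count))
  panels <- sets[ord][seq_len(min(top_panels, length(sets)))]
  structure(list(frequency = freq, panels = panels, n_reps = n_reps),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat("Candidate ranking over", x$n_reps, "forest repetitions;",
      length(x$panels), "seed panels\nTop features:\n")
  print(head(x$frequency, 10))
  invisible(x)
}

#' Enumerate unique subpanels
#'
#' All feature subsets of sizes `min_size` to `max_size` of each seed
#' panel, deduplicated globally and returned in deterministic order
#' (by size, then lexically).
#'
#' @param seed_panels list of character vectors (or a single vector).
#' @param min_size,max_size subset size bounds (2 and 10 by default; no
#'   emitted subset ever exceeds 10 features).
#' @return list of character vectors, each sorted.
#' @export
enumerate_subpanels <- function(seed_panels, min_size = 2L, max_size = 10L) {
  if (!is.list(seed_panels)) seed_panels <- list(seed_panels)
  max_size <- min(max_size, 10L)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (panel in seed_panels) {
    panel <- sort(unique(panel))
    if (length(panel) < min_size) {
      stop("seed panel smaller than min_size: ", paste(panel, collapse = ", "))
    }
    for (k in seq(min_size, min(max_size, length(panel)))) {
      subsets <- combn(panel, k, simplify = FALSE)
      for (s in subsets) {
        key <- paste(s, collapse = "|")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- s
        }
      }
    }
  }
  sizes <- lengths(out)
  keys <- vapply(out, paste, "", collapse = "|")
  out[order(sizes, keys)]
}

#' Maximum-likelihood logistic panel fit
#'
#' Fits the panel's logistic model by maximum likelihood and reports
#' McFadden's pseudo R-squared (`1 - lnL_model / lnL_null`) and the
#' likelihood-ratio chi-squared p-value against the intercept-only model.
#' Perfectly separated panels are refitted with a small ridge penalty
#' (default 1e-4) to keep coefficients finite and flagged `separable`.
#'
#' @param x feature matrix, samples x features.
#' @param y binary outcome.
#' @param features panel feature IDs (columns of `x`).
#' @param ridge penalty used only on separation.
#' @return list of class `panel_fit`: `model` (a [panel_model()]),
#'   `mcfadden_r2`, `fit_p`, `logLik`, `separable`.
#' @export
fit_logistic <- function(x, y, features = colnames(x), ridge = 1e-4) {
  y <- as.logical(y)
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  x <- as.matrix(x)
  stopifnot(all(features %in% colnames(x)))
  xm <- x[, features, drop = FALSE]
  k <- length(features)

  loglik <- function(eta) sum(ifelse(y, log(plogis(eta)), log1p(-plogis(eta))))
  p0 <- mean(y)
  ll0 <- sum(y) * log(p0) + sum(!y) * log(1 - p0)

  separable <- FALSE
  if (k == 0L) {
    beta <- numeric(0)
    a <- log(p0 / (1 - p0))
    ll <- ll0
  } else {
    df <- data.frame(.y = y, xm, check.names = FALSE)
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      glm(.y ~ ., data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                  conditionMessage(w))) {
          sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    # near-zero deviance means the classes are perfectly separated even
    # when glm converges without complaint
    if (sep_warn || !fit$converged || fit$deviance < 1e-6 ||
        any(abs(coef(fit)) > 1e3)) {
      separable <- TRUE
      cf <- ridge_logistic(xm, y, lambda = ridge)
    } else {
      cf <- coef(fit)
    }
    a <- unname(cf[1])
    beta <- unname(cf[-1])
    ll <- loglik(a + drop(xm %*% beta))
  }
  model <- panel_model(features, a, beta)
  r2 <- if (k == 0L) 0 else max(0, 1 - ll / ll0)
  fit_p <- if (k == 0L) 1 else
    pchisq(2 * (ll - ll0), df = k, lower.tail = FALSE)
  structure(list(model = model, mcfadden_r2 = r2, fit_p = fit_p,
                 logLik = ll, separable = separable),
            class = "panel_fit")
}

# Ridge-penalised IRLS (no penalty on the intercept); used only as the
# separation guard.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100L, tol = 1e-10) {
  X <- cbind(1, x)
  pen <- diag(c(0, rep(lambda, ncol(x))))
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new_beta <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  drop(beta)
}

#' Evaluate a panel by repeated stratified 70:30 splits (RSBMR)
#'
#' Random Single Bin Multiple Repeats: for each of `n_repeats`
#' repetitions the cohort is split (stratified on outcome) into a
#' training fraction `split` and a test remainder; the panel's logistic
#' model is fitted on the training set and scored on the test set (AUC,
#' and sensitivity/specificity at the Youden-optimal threshold). Means
#' over repetitions are reported, alongside the full-cohort fit quality.
#'
#' @param x feature matrix, samples x features.
#' @param y binary outcome.
#' @param features panel feature IDs.
#' @param split training fraction (default 0.70).
#' @param n_repeats split repetitions (default 10).
#' @param seed integer seed.
#' @return object of class `panel_evaluation` with `method = "RSBMR"`,
#'   `features`, `mean_auc`, `auc_ci` (2.5/97.5 percentiles over
#'   repetitions), `sensitivity`, `specificity`, `mcfadden_r2`, `fit_p`,
#'   `separable`, `n_iterations`, `model` (full-cohort fit).
#' @export
evaluate_rsbmr <- function(x, y, features, split = 0.70, n_repeats = 10L,
                           seed = NULL) {
  y <- as.logical(y)
  x <- as.matrix(x)
  n1 <- sum(y)
  n0 <- sum(!y)
  tr1 <- round(split * n1)
  tr0 <- round(split * n0)
  if (min(tr1, tr0) < 1L || min(n1 - tr1, n0 - tr0) < 1L) {
    stop("classes too small for a stratified ", split, " split")
  }
  restore <- set_local_seed(seed)
  on.exit(restore())

  aucs <- sens <- spec <- numeric(n_repeats)
  pos_idx <- which(y)
  neg_idx <- which(!y)
  for (r in seq_len(n_repeats)) {
    train <- c(sample(pos_idx, tr1), sample(neg_idx, tr0))
    test <- setdiff(seq_along(y), train)
    fit <- fit_logistic(x[train, , drop = FALSE], y[train], features)
    scores <- predict(fit$model, x[test, , drop = FALSE])
    aucs[r] <- rank_auc(scores, y[test])
    ss <- youden_sens_spec(scores, y[test])
    sens[r] <- ss["sens"]
    spec[r] <- ss["spec"]
  }
  full <- fit_logistic(x, y, features)
  structure(
    list(method = "RSBMR", features = sort(features),
         mean_auc = mean(aucs), auc_ci = quantile(aucs, c(0.025, 0.975), names = FALSE),
         per_iteration_auc = aucs,
         sensitivity = mean(sens), specificity = mean(spec),
         mcfadden_r2 = full$mcfadden_r2, fit_p = full$fit_p,
         separable = full$separable, n_iterations = n_repeats,
         model = full$model),
    class = "panel_evaluation"
  )
}

#' Evaluate a panel by stratified k-fold cross-validation
#'
#' Stratified k-fold: each fold is held out in turn, the panel model is
#' fitted on the remaining folds and the held-out AUC recorded; the mean
#' per-fold AUC is reported. A fold that ends up single-class has no
#' defined AUC: it is skipped, counted, and a warning is raised.
#' Sensitivity/specificity come from the pooled out-of-fold predictions
#' at the Youden-optimal threshold.
#'
#' @inheritParams evaluate_rsbmr
#' @param k number of folds (default 10; must be < n so every fold can
#'   hold more than one sample).
#' @return object of class `panel_evaluation` with `method = "kfold"`.
#' @export
evaluate_kfold <- function(x, y, features, k = 10L, seed = NULL) {
  y <- as.logical(y)
  x <- as.matrix(x)
  n <- length(y)
  if (k >= n) {
    stop("k must be smaller than the cohort size: single-sample folds have ",
         "no defined AUC")
  }
  if (k < 2L) stop("k must be at least 2")
  restore <- set_local_seed(seed)
  on.exit(restore())

  fold <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  aucs <- rep(NA_real_, k)
  pooled_scores <- rep(NA_real_, n)
  skipped <- 0L
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    fit <- fit_logistic(x[train, , drop = FALSE], y[train], features)
    scores <- predict(fit$model, x[test, , drop = FALSE])
    pooled_scores[test] <- scores
    if (length(unique(y[test])) < 2L) {
      skipped <- skipped + 1L
      next
    }
    aucs[f] <- rank_auc(scores, y[test])
  }
  if (skipped > 0L) {
    warning(skipped, " fold(s) held a single class; their AUC is undefined ",
            "and they were skipped")
  }
  aucs <- aucs[!is.na(aucs)]
  full <- fit_logistic(x, y, features)
  ss <- youden_sens_spec(pooled_scores, y)
  structure(
    list(method = "kfold", features = sort(features),
         mean_auc = mean(aucs), auc_ci = quantile(aucs, c(0.025, 0.975), names = FALSE),
         per_iteration_auc = aucs,
         sensitivity = unname(ss["sens"]), specificity = unname(ss["spec"]),
         mcfadden_r2 = full$mcfadden_r2, fit_p = full$fit_p,
         separable = full$separable, n_iterations = length(aucs),
         model = full$model),
    class = "panel_evaluation"
  )
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("[%s] %d-feature panel {%s}: mean AUC %.3f (CI %.3f-%.3f), sens %.2f / spec %.2f, McFadden R2 %.3f, fit p %.3g\n",
              x$method, length(x$features), paste(x$features, collapse = ", "),
              x$mean_auc, x$auc_ci[1], x$auc_ci[2], x$sensitivity,
              x$specificity, x$mcfadden_r2, x$fit_p))
  invisible(x)
}

#' Screen evaluated panels
#'
#' Retains panels with mean AUC strictly greater than `auc_min` and fit
#' p-value below `p_max`, ranked by mean AUC (descending), breaking ties
#' by fewer features then lexical feature order.
#'
#' @param evaluations list of `panel_evaluation` objects.
#' @param auc_min AUC threshold (strict `>`, default 0.80).
#' @param p_max fit p-value threshold (default 0.05).
#' @return data frame summary (one row per retained panel, best first)
#'   with the retained evaluations as attribute `"evaluations"`.
#' @export
screen_panels <- function(evaluations, auc_min = 0.80, p_max = 0.05) {
  stopifnot(length(evaluations) >= 1L)
  keep <- vapply(evaluations, function(e) {
    e$mean_auc > auc_min && e$fit_p < p_max
  }, logical(1))
  kept <- evaluations[keep]
  if (!length(kept)) {
    out <- data.frame(panel = character(0), n_features = integer(0),
                      method = character(0), mean_auc = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      mcfadden_r2 = numeric(0), fit_p = numeric(0))
    attr(out, "evaluations") <- list()
    return(out)
  }
  key <- vapply(kept, function(e) paste(e$features, collapse = "|"), "")
  ord <- order(-vapply(kept, `[[`, numeric(1), "mean_auc"),
               vapply(kept, function(e) length(e$features), integer(1)),
               key)
  kept <- kept[ord]
  out <- data.frame(
    panel = vapply(kept, function(e) paste(e$features, collapse = ","), ""),
    n_features = vapply(kept, function(e) length(e$features), integer(1)),
    method = vapply(kept, `[[`, "", "method"),
    mean_auc = vapply(kept, `[[`, numeric(1), "mean_auc"),
    sensitivity = vapply(kept, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(kept, `[[`, numeric(1), "specificity"),
    mcfadden_r2 = vapply(kept, `[[`, numeric(1), "mcfadden_r2"),
    fit_p = vapply(kept, `[[`, numeric(1), "fit_p")
  )
  attr(out, "evaluations") <- kept
  out
}

#' Wrapper biomarker-panel discovery (2BDP)
#'
#' The full panel search: random-forest candidate ranking over repeated
#' bootstrap forests, exhaustive enumeration of 2-10-feature subpanels of
#' the top-ranked seed panels, logistic fitting of every subpanel, and
#' cross-validated evaluation by repeated stratified 70:30 splits
#' (RSBMR), stratified k-fold, or both. Panels passing the AUC and fit
#' screens are ranked and returned as a classed model object.
#'
#' @param x feature matrix, samples (animals) x features -- typically
#'   [panel_input_matrix()] output restricted to the conserved set.
#' @param y binary outcome (survival).
#' @param method evaluation route(s): `"kfold"`, `"rsbmr"` or both.
#' @param n_reps,top_panels,panel_size,num_trees forest-ranking settings,
#'   see [rank_candidates_rf()] (study defaults 2000 / 200 / 10).
#' @param min_size,max_size subpanel size bounds (2-10).
#' @param split,n_repeats RSBMR settings; `k` k-fold setting.
#' @param auc_min,p_max screening thresholds (AUC strictly > 0.80,
#'   fit p < 0.05).
#' @param seed integer seed governing every stochastic step.
#' @return object of class `bdp`: `ranking` (candidate frequencies and
#'   seed panels), `evaluations` (all subpanel evaluations), `screened`
#'   (ranked summary of passing panels), `best` (top evaluation or
#'   `NULL`), plus the call settings.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_features = 30, seed = 3))
#' counts <- prefilter_features(cohort$counts)
#' fc <- log2fc_baseline(cpm_matrix(counts, tmm_factors(counts)),
#'                       cohort$metadata)
#' pin <- panel_input_matrix(fc)
#' fitd <- discover_panels(pin$x, pin$y, n_reps = 25, top_panels = 5,
#'                         panel_size = 5, max_size = 3, seed = 1)
#' print(fitd)
#' }
#' @export
discover_panels <- function(x, y, method = c("kfold", "rsbmr"),
                            n_reps = 2000L, top_panels = 200L,
                            panel_size = 10L, num_trees = 100L,
                            min_size = 2L, max_size = 10L,
                            split = 0.70, n_repeats = 10L, k = 10L,
                            auc_min = 0.80, p_max = 0.05, seed = NULL) {
  method <- match.arg(method, c("kfold", "rsbmr"), several.ok = TRUE)
  x <- as.matrix(x)
  y <- as.logical(y)
  seed <- seed %||% sample.int(1e6, 1)

  ranking <- rank_candidates_rf(x, y, n_reps = n_reps, top_panels = top_panels,
                                panel_size = panel_size, num_trees = num_trees,
                                seed = seed)
  subpanels <- enumerate_subpanels(ranking$panels, min_size, max_size)
  evaluations <- list()
  for (i in seq_along(subpanels)) {
    for (mth in method) {
      ev <- if (mth == "kfold") {
        evaluate_kfold(x, y, subpanels[[i]], k = k, seed = seed + i)
      } else {
        evaluate_rsbmr(x, y, subpanels[[i]], split = split,
                       n_repeats = n_repeats, seed = seed + i)
      }
      evaluations[[length(evaluations) + 1L]] <- ev
    }
  }
  screened <- screen_panels(evaluations, auc_min = auc_min, p_max = p_max)
  best <- attr(screened, "evaluations")
  best <- if (length(best)) best[[1]] else NULL
  structure(
    list(ranking = ranking, evaluations = evaluations, screened = screened,
         best = best, method = method, n_subpanels = length(subpanels),
         auc_min = auc_min, p_max = p_max, seed = seed,
         n_samples = nrow(x), n_features = ncol(x)),
    class = "bdp"
  )
}

#' @export
print.bdp <- function(x, ...) {
  cat("2BDP panel discovery:", x$n_features, "candidate features,",
      x$n_samples, "samples;", x$n_subpanels, "subpanels evaluated by",
      paste(x$method, collapse = " + "), "\n")
  if (is.null(x$best)) {
    cat(sprintf("No panel passed the screen (AUC > %.2f and fit p < %.2g)\n",
                x$auc_min, x$p_max))
  } else {
    cat(nrow(x$screened), "panel(s) passed the screen; best:\n")
    print(x$best)
  }
  invisible(x)
}

#' @export
summary.bdp <- function(object, n = 10L, ...) {
  cat("Top candidate features by forest selection frequency:\n")
  print(head(object$ranking$frequency, n))
  cat("\nScreened panels (best first):\n")
  print(head(object$screened, n), row.names = FALSE)
  invisible(object$screened)
}

#' @export
predict.bdp <- function(object, newdata, type = c("link", "response"), ...) {
  if (is.null(object$best)) stop("no panel passed the screen; nothing to predict with")
  predict(object$best$model, newdata, type = match.arg(type))
}

#' @export
coef.bdp <- function(object, ...) {
  if (is.null(object$best)) return(NULL)
  coef(object$best$model)
}
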