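test_that("panel models evaluate the printed worked examples", {
  p <- published_rrif_panels()
  x3 <- setNames(rep(0, 3), p$kfold_3mir$features)
  x7 <- setNames(rep(0, 7), p$rsbmr_7mir$features)
  expect_equal(unname(predict(p$kfold_3mir, x3)), 0.58)
  expect_equal(unname(predict(p$rsbmr_7mir, x7)), 0.19)
  expect_equal(unname(predict(p$kfold_3mir, x3, type = "response")),
               plogis(0.58))
  # zero log-odds maps to probability one half
  m <- panel_model(c("a", "b"), 0, c(1, -1))
  expect_equal(unname(predict(m, c(a = 1, b = 1), type = "response")), 0.5)
  # misaligned features rejected; coef returns intercept plus coefficients
  expect_error(predict(m, c(a = 1)), "every panel feature")
  expect_equal(coef(p$kfold_3mir)[["(Intercept)"]], 0.58)
  expect_error(panel_model("a", 1, c(1, 2)), "length")
})

test_that("predicted probability is increasing in each linear term", {
  m <- panel_model(c("a", "b"), 0.2, c(0.8, -1.1))
  grid <- seq(-3, 3, length.out = 25)
  pa <- predict(m, cbind(a = grid, b = 0), type = "response")
  pb <- predict(m, cbind(a = 0, b = grid), type = "response")
  expect_true(all(diff(pa) > 0))
  expect_true(all(diff(pb) < 0))
  expect_true(all(pa > 0 & pa < 1))
})

test_that("subpanel enumeration is exhaustive, bounded and deduplicated", {
  subs <- enumerate_subpanels(letters[1:4], min_size = 2, max_size = 4)
  expect_length(subs, choose(4, 2) + choose(4, 3) + choose(4, 4))  # 11
  expect_identical(enumerate_subpanels(c("a", "b")), list(c("a", "b")))
  # global dedup across overlapping seed panels, deterministic order
  s2 <- enumerate_subpanels(list(c("a", "b", "c"), c("b", "c", "d")),
                            min_size = 2, max_size = 3)
  keys <- vapply(s2, paste, "", collapse = "|")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(s2, enumerate_subpanels(list(c("c", "b", "a"), c("d", "c", "b")),
                                           min_size = 2, max_size = 3))
  # no subset ever exceeds 10 features
  s3 <- enumerate_subpanels(letters[1:12], min_size = 2, max_size = 12)
  expect_lte(max(lengths(s3)), 10)
  expect_error(enumerate_subpanels("a"), "min_size")
})

test_that("logistic fits match an independent IRLS oracle", {
  set.seed(27)
  for (i in 1:5) {
    n <- 60
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    eta <- 0.3 + X %*% c(1, -0.8, 0.4)
    y <- runif(n) < plogis(eta)
    fit <- fit_logistic(X, y)
    oracle <- irls_logistic(X, y)
    expect_equal(unname(coef(fit$model)), unname(oracle), tolerance = 1e-6)
  }
})

test_that("fit quality statistics behave at their reference points", {
  set.seed(28)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(TRUE, FALSE), 20)
  # intercept-only model compared with itself: McFadden exactly zero
  f0 <- fit_logistic(X, y, features = character(0))
  expect_identical(f0$mcfadden_r2, 0)
  expect_identical(f0$fit_p, 1)
  f <- fit_logistic(X, y)
  expect_gte(f$mcfadden_r2, 0)
  expect_lt(f$mcfadden_r2, 1)
  expect_false(f$separable)
  expect_error(fit_logistic(X, rep(TRUE, 40)), "both classes")
  # perfect separation is ridge-guarded and flagged
  Xs <- cbind(a = c(rep(-2, 20), rep(2, 20)), b = rnorm(40))
  fs <- fit_logistic(Xs, rep(c(FALSE, TRUE), each = 20))
  expect_true(fs$separable)
  expect_true(all(is.finite(coef(fs$model))))
})

test_that("forest ranking puts a perfectly separating feature first", {
  set.seed(29)
  wins <- 0L
  for (i in 1:5) {
    n <- 40
    X <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- rep(c(TRUE, FALSE), each = n / 2)
    X[, "f4"] <- ifelse(y, 3, -3) + rnorm(n, 0, 0.1)
    rk <- rank_candidates_rf(X, y, n_reps = 30, top_panels = 5,
                             panel_size = 3, num_trees = 50, seed = 40 + i)
    if (names(rk$frequency)[1] == "f4") wins <- wins + 1L
  }
  expect_equal(wins, 5L)
})

test_that("forest ranking frequencies and null behaviour are sane", {
  set.seed(30)
  X <- matrix(rnorm(36 * 6), 36, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(TRUE, FALSE), 18)
  rk1 <- rank_candidates_rf(X, y, n_reps = 1, top_panels = 3, panel_size = 3,
                            num_trees = 20, seed = 1)
  expect_true(all(rk1$frequency %in% c(0, 1)))
  expect_error(rank_candidates_rf(X, rep(TRUE, 36), n_reps = 2), "both classes")
  # permuted outcomes: no feature is preferred under the null. Repetitions
  # within one call share the same (X, y) draw and are highly correlated,
  # so the independent unit is a whole ranking run on fresh null data; each
  # run contributes its top features once.
  counts <- setNames(numeric(ncol(X)), colnames(X))
  for (i in 1:12) {
    Xi <- matrix(rnorm(36 * 6), 36, 6, dimnames = dimnames(X))
    rk0 <- rank_candidates_rf(Xi, sample(y), n_reps = 25, top_panels = 5,
                              panel_size = 3, num_trees = 50, seed = 2 + i)
    top3 <- names(rk0$frequency)[1:3]
    counts[top3] <- counts[top3] + 1
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("RSBMR evaluation recovers a planted panel and is reproducible", {
  aucs <- numeric(5)
  for (i in 1:5) {
    x <- sim_fc(900 + i, n_features = 30)
    pin <- panel_input_matrix(x$fc)
    ev <- evaluate_rsbmr(pin$x, pin$y, x$truth$survival_panel$feature,
                         seed = i)
    aucs[i] <- ev$mean_auc
    expect_equal(ev$n_iterations, 10)
    expect_true(ev$auc_ci[1] <= ev$auc_ci[2])
  }
  expect_gte(mean(aucs), 0.85)
  # determinism under a fixed seed
  x <- sim_fc(910, n_features = 30)
  pin <- panel_input_matrix(x$fc)
  e1 <- evaluate_rsbmr(pin$x, pin$y, x$truth$survival_panel$feature,
                       n_repeats = 1, seed = 9)
  e2 <- evaluate_rsbmr(pin$x, pin$y, x$truth$survival_panel$feature,
                       n_repeats = 1, seed = 9)
  expect_identical(e1$per_iteration_auc, e2$per_iteration_auc)
  # classes too small to stratify are rejected
  expect_error(evaluate_rsbmr(pin$x[1:4, ], c(TRUE, FALSE, FALSE, FALSE),
                              x$truth$survival_panel$feature),
               "stratified")
})

test_that("k-fold evaluation separates a separable panel and guards folds", {
  set.seed(31)
  n <- 36
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(TRUE, FALSE), each = 18)
  X[, 1] <- ifelse(y, 2, -2) + rnorm(n, 0, 0.1)
  ev <- evaluate_kfold(X, y, c("f1", "f2"), k = 6, seed = 5)
  expect_gte(ev$mean_auc, 0.95)
  # leave-one-out rejected: single-sample folds have no AUC
  expect_error(evaluate_kfold(X, y, c("f1", "f2"), k = n), "smaller")
  # same seed => identical folds and results
  e1 <- evaluate_kfold(X, y, c("f1", "f2"), k = 6, seed = 7)
  e2 <- evaluate_kfold(X, y, c("f1", "f2"), k = 6, seed = 7)
  expect_identical(e1$per_iteration_auc, e2$per_iteration_auc)
  # a fold holding one class is skipped with a warning
  y_skew <- c(rep(TRUE, 3), rep(FALSE, 33))
  expect_warning(evaluate_kfold(X, y_skew, c("f1", "f2"), k = 12, seed = 8),
                 "single class")
})

test_that("RSBMR and k-fold agree on planted-signal data", {
  diffs <- numeric(6)
  for (i in 1:6) {
    x <- sim_fc(920 + i, n_features = 30)
    pin <- panel_input_matrix(x$fc)
    feats <- x$truth$survival_panel$feature
    a <- evaluate_rsbmr(pin$x, pin$y, feats, seed = i)$mean_auc
    b <- evaluate_kfold(pin$x, pin$y, feats, seed = i)$mean_auc
    diffs[i] <- abs(a - b)
  }
  expect_true(all(diffs <= 0.10))
})

test_that("panel screening applies strict thresholds and deterministic order", {
  mk <- function(auc, p, feats, method = "kfold") {
    structure(list(method = method, features = feats, mean_auc = auc,
                   auc_ci = c(auc, auc), sensitivity = 1, specificity = 1,
                   mcfadden_r2 = 0.5, fit_p = p, n_iterations = 10),
              class = "panel_evaluation")
  }
  evs <- list(mk(0.80, 0.001, c("a", "b")),     # AUC exactly 0.80: excluded
              mk(0.90, 0.001, c("c", "d")),
              mk(0.90, 0.001, c("a", "c")),
              mk(0.85, 0.20, c("e", "f")),      # fit p too large
              mk(0.82, 0.01, c("a", "b", "c")))
  out <- screen_panels(evs)
  expect_equal(out$panel, c("a,c", "c,d", "a,b,c"))
  expect_true(all(diff(out$mean_auc) <= 0))
  # an empty survivor list is allowed
  none <- screen_panels(list(mk(0.5, 0.5, c("a", "b"))))
  expect_equal(nrow(none), 0)
})

test_that("the full panel search is deterministic and returns a model object", {
  x <- sim_fc(930, n_features = 30)
  pin <- panel_input_matrix(x$fc)
  run <- function() {
    discover_panels(pin$x, pin$y, method = "rsbmr", n_reps = 15,
                    top_panels = 4, panel_size = 4, max_size = 3,
                    num_trees = 40, seed = 77)
  }
  b1 <- run()
  b2 <- run()
  expect_identical(b1$screened, b2$screened)
  expect_s3_class(b1, "bdp")
  expect_false(is.null(b1$best))
  pred <- predict(b1, pin$x, type = "response")
  expect_true(all(pred >= 0 & pred <= 1))  # may saturate in double precision
  expect_equal(length(coef(b1)), length(b1$best$features) + 1)
})
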