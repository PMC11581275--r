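test_that("a strong sex-only marker is attributed to Sex, not dose", {
  sex_p <- rd_p <- numeric(20)
  for (r in 1:20) {
    n <- 25
    ids <- feature_ids(n)
    truth <- planted_truth(sex_markers = data.frame(
      feature = ids[1], sex = "M", effect = 1.5))
    cohort <- simulate_cohort(sim_config(n_features = n, planted = truth,
                                         seed = 700 + r))
    kept <- prefilter_features(cohort$counts)
    fc <- log2fc_baseline(cpm_matrix(kept, tmm_factors(kept)), cohort$metadata)
    res <- fit_four_way_anova(fc)
    one <- res[res$feature == ids[1], ]
    sex_p[r] <- one$p[one$term == "Sex"]
    rd_p[r] <- one$p[one$term == "RD"]
  }
  expect_lt(median(sex_p), 0.05)
  expect_gt(mean(sex_p < 0.05), 0.8)
  expect_gt(median(rd_p), 0.05)
})

test_that("constant features yield F = 0 and p = 1 on every term", {
  meta <- toy_meta()
  fc <- matrix(c(rep(2, nrow(meta)), rnorm(nrow(meta))), nrow = 2, byrow = TRUE,
               dimnames = list(c("const", "noise"), meta$sample_id))
  res <- fit_four_way_anova(fc, meta)
  const <- res[res$feature == "const" & res$estimable, ]
  expect_true(all(const$F == 0))
  expect_true(all(const$p == 1))
})

test_that("term and residual sums of squares decompose the total", {
  meta <- toy_meta(doses = c(6, 7), n_per = 2)  # balanced full factorial
  set.seed(4)
  fc <- matrix(rnorm(5 * nrow(meta)), nrow = 5,
               dimnames = list(paste0("f", 1:5), meta$sample_id))
  res <- fit_four_way_anova(fc, meta)
  expect_true(all(res$estimable))
  for (f in rownames(fc)) {
    sub <- res[res$feature == f, ]
    total <- attr(res, "ss_total")[f]
    decomposed <- sum(sub$ss) +
      attr(res, "ss_resid_between")[f] +
      attr(res, "ss_resid_within")[f]
    expect_equal(unname(decomposed), unname(total), tolerance = 1e-8)
  }
})

test_that("between-animal Type II tests agree with the car oracle", {
  skip_if_not_installed("car")
  # unbalanced between design: drop two animals
  meta <- toy_meta(doses = c(6, 7), n_per = 3)
  keep <- meta$animal_id != "T01" & meta$animal_id != "T10"
  meta <- meta[keep, ]
  set.seed(9)
  y <- rnorm(nrow(meta)) + (meta$dose_gy - 6) * 0.8 + (meta$sex == "M")
  fc <- matrix(y, nrow = 1, dimnames = list("f1", meta$sample_id))
  res <- fit_four_way_anova(fc, meta)

  agg <- aggregate(y, by = list(animal_id = meta$animal_id), FUN = mean)
  cov <- meta[match(agg$animal_id, meta$animal_id), ]
  dfm <- data.frame(y = agg$x, RD = factor(cov$dose_gy), Sex = factor(cov$sex),
                    RRiF = factor(cov$survived))
  ca <- car::Anova(lm(y ~ RD * Sex * RRiF, dfm), type = 2)
  for (term in c("RD", "Sex", "RRiF", "RD:Sex")) {
    mine <- res[res$feature == "f1" & res$term == term, ]
    expect_equal(mine$F, ca[term, "F value"], tolerance = 1e-8)
    expect_equal(mine$p, ca[term, "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("p-values are uniform under an independent-noise null", {
  meta <- toy_meta(doses = c(6, 6.5, 7, 7.5), n_per = 2)
  set.seed(12)
  fc <- matrix(rnorm(400 * nrow(meta)), nrow = 400,
               dimnames = list(paste0("f", 1:400), meta$sample_id))
  res <- fit_four_way_anova(fc, meta)
  for (term in c("RD", "TSI", "Sex", "RD:TSI")) {
    p <- res$p[res$term == term & res$estimable]
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  }
})

test_that("inestimable terms are flagged, not silently dropped", {
  meta <- toy_meta()
  meta$sex <- "M"  # single observed level
  set.seed(3)
  fc <- matrix(rnorm(2 * nrow(meta)), nrow = 2,
               dimnames = list(c("a", "b"), meta$sample_id))
  res <- fit_four_way_anova(fc, meta)
  sex_terms <- grepl("Sex", res$term)
  expect_true(all(!res$estimable[sex_terms]))
  expect_true(all(is.na(res$p[sex_terms])))
  expect_true(all(res$estimable[res$term == "RD"]))
  expect_setequal(unique(res$term), attr(terms(~ RD * TSI * Sex * RRiF),
                                         "term.labels"))
})

test_that("DE union pools significant features without duplicates", {
  x <- sim_fc(21, n_features = 40)
  res <- fit_four_way_anova(x$fc)
  de <- curate_de_union(res)
  expect_false(anyDuplicated(de$union) > 0)
  expect_lte(length(de$union), sum(de$counts))
  expect_setequal(de$union, unique(unlist(de$per_term)))
  # invariant under permutation of term order
  perm <- res[order(res$term, res$feature), ]
  attr(perm, "alpha") <- attr(res, "alpha")
  expect_setequal(curate_de_union(perm)$union, de$union)
  # no significant features -> empty union, still a valid report
  res0 <- res
  res0$p <- 0.99
  expect_length(curate_de_union(res0)$union, 0)
})

test_that("effect size summary matches direct recomputation", {
  fake <- data.frame(feature = "f", term = c("RD", "TSI", "Sex"),
                     eta_sq = c(0.2, 0.2, 0.2), estimable = TRUE)
  s <- effect_size_summary(fake)
  expect_equal(s$mean_eta_sq, 0.2)
  expect_equal(s$cv_eta_sq, 0)
  expect_equal(effect_size_summary(fake[1, ])$cv_eta_sq, 0)
  x <- sim_fc(22, n_features = 30)
  res <- fit_four_way_anova(x$fc)
  s2 <- effect_size_summary(res)
  eta <- res$eta_sq[res$estimable]
  expect_equal(s2$mean_eta_sq, mean(eta))
  expect_equal(s2$cv_eta_sq, sd(eta) / mean(eta))
  expect_error(effect_size_summary(data.frame(eta_sq = 1, estimable = FALSE)),
               "no estimable")
})

test_that("simulated power approaches alpha at zero effect and is monotone", {
  d <- default_study_design()
  p0 <- estimate_power_by_simulation(d, 1e-6, n_reps = 300, seed = 5)
  expect_lt(abs(p0$estimated_power - 0.05), 0.04)
  grid <- vapply(c(0.05, 0.15, 0.30), function(e) {
    estimate_power_by_simulation(d, e, n_reps = 150, seed = 6)$estimated_power
  }, numeric(1))
  expect_true(all(diff(grid) >= 0))
  # monotone non-decreasing in animals per group
  big <- study_design(d$groups$dose_gy, d$groups$n_animals * 3L,
                      d$groups$n_male * 3L, d$groups$n_female * 3L,
                      d$groups$n_survived * 3L)
  p_small <- estimate_power_by_simulation(d, 0.08, n_reps = 150, seed = 7)
  p_big <- estimate_power_by_simulation(big, 0.08, n_reps = 150, seed = 7)
  expect_gte(p_big$estimated_power, p_small$estimated_power)
})
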