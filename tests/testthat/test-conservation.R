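test_that("pairwise alignment reproduces closed-form scores and identities", {
  a <- align_pair("ACGU", "ACGU")
  expect_equal(a$score, 20)
  expect_equal(a$pct_identity, 100)
  # self-identity is 100% across the mature length range
  set.seed(14)
  for (len in c(18L, 22L, 30L)) {
    s <- random_rna(len)
    self <- align_pair(s, s)
    expect_equal(self$pct_identity, 100)
    expect_equal(self$score, 5 * len)
  }
  # T accepted and mapped to U
  expect_equal(align_pair("ACGT", "ACGU")$pct_identity, 100)
  expect_error(align_pair("", "ACGU"), "empty")
  expect_error(align_pair("ACGX", "ACGU"), "alphabet")
})

test_that("alignment score is symmetric for symmetric substitution scores", {
  set.seed(15)
  for (i in 1:20) {
    a <- random_rna(sample(18:30, 1))
    b <- random_rna(sample(18:30, 1))
    expect_lt(abs(align_pair(a, b)$score - align_pair(b, a)$score), 2e-5)
  }
})

test_that("dynamic-programming scores equal exhaustive enumeration", {
  set.seed(16)
  for (i in 1:60) {
    a <- random_rna(sample(2:8, 1))
    b <- random_rna(sample(2:8, 1))
    expect_lt(abs(align_pair(a, b)$score - brute_align_score(a, b)), 2e-5)
  }
})

test_that("top_match returns all tied best targets ordered by ID", {
  q <- c(q1 = "ACGUACGUACGUACGUACGU")
  refs <- c(zz = "ACGUACGUACGUACGUACGU",
            aa = "ACGUACGUACGUACGUACGU",
            mm = "UUUUUUUUUUUUUUUUUUUU")
  tm <- top_match(q, refs)
  expect_equal(tm$target, c("aa", "zz"))
  expect_equal(tm$pct_identity, c(100, 100))
  # single exact reference
  tm1 <- top_match(q, refs[c("zz", "mm")])
  expect_equal(tm1$target, "zz")
  # best-by-score agrees with the brute-force oracle on short references
  set.seed(17)
  for (i in 1:10) {
    qq <- setNames(random_rna(6), "q")
    rr <- setNames(vapply(1:5, function(j) random_rna(sample(3:7, 1)), ""),
                   paste0("r", 1:5))
    tm2 <- top_match(qq, rr)
    oracle <- vapply(rr, function(s) brute_align_score(qq, s), numeric(1))
    expect_lt(abs(max(oracle) - tm2$score[1]), 2e-5)
    expect_true(all(tm2$target %in% names(oracle)[oracle >= max(oracle) - 1e-4]))
  }
})

test_that("sc curation recovers exactly the planted homologues", {
  x <- sim_fc(33, n_features = 40)
  cfg <- sim_config(n_features = 40, seed = 33)
  fsim <- simulate_mirna_fasta(cfg, n_decoys_b = 10)
  de <- curate_de_union(fit_four_way_anova(x$fc))
  sc <- curate_sc(de$union, fsim$seq_a, fsim$seq_b, min_identity = 90)
  expect_setequal(sc$sc, intersect(de$union, fsim$pairs$feature_a))
  # min_identity 0: every DE feature with any alignment
  sc0 <- curate_sc(de$union, fsim$seq_a, fsim$seq_b, min_identity = 0)
  expect_setequal(sc0$sc, de$union)
  # min_identity above 100: empty set
  sc101 <- curate_sc(de$union, fsim$seq_a, fsim$seq_b, min_identity = 101)
  expect_length(sc101$sc, 0)
  # DE feature missing from the FASTA is excluded with a message
  expect_message(
    curate_sc(c(de$union, "ghost"), fsim$seq_a, fsim$seq_b),
    "absent")
})

test_that("fs curation against the identity reference reproduces the DE union", {
  x <- sim_fc(34, n_features = 40)
  cfg <- sim_config(n_features = 40, seed = 34)
  fsim <- simulate_mirna_fasta(cfg)
  de <- curate_de_union(fit_four_way_anova(x$fc))
  fs <- curate_fs(x$kept, x$cohort$metadata, fsim$seq_a, fsim$seq_a)
  expect_setequal(fs$fs, de$union)
  # and the full intersection equals the DE union too
  sc <- curate_sc(de$union, fsim$seq_a, fsim$seq_a, min_identity = 90)
  cn <- intersect_sets(sc, fs)
  expect_setequal(cn$cnvd, de$union)
  # reference with a single human ID: fs is a subset of that ID
  one_ref <- fsim$seq_a[1]
  names(one_ref) <- "hsa-only"
  fs1 <- curate_fs(x$kept, x$cohort$metadata, fsim$seq_a, one_ref,
                   min_identity = 0)
  expect_true(all(fs1$fs %in% "hsa-only"))
})

test_that("planted conserved markers survive human re-assignment", {
  hits <- 0L
  total <- 0L
  for (r in 1:10) {
    x <- sim_fc(800 + r, n_features = 40)
    cfg <- sim_config(n_features = 40, seed = 800 + r)
    fsim <- simulate_mirna_fasta(cfg, n_decoys_b = 10)
    fs <- curate_fs(x$kept, x$cohort$metadata, fsim$seq_a, fsim$seq_b)
    planted <- c(x$truth$time_markers$feature, x$truth$survival_panel$feature)
    mapped <- fsim$pairs$feature_b[match(planted, fsim$pairs$feature_a)]
    total <- total + length(mapped)
    hits <- hits + sum(mapped %in% fs$fs)
  }
  expect_gte(hits / total, 0.8)
})

test_that("cnvd set obeys the intersection bounds", {
  map <- data.frame(query = c("a", "b", "c"), target = c("ha", "hb", "hc"),
                    pct_identity = 100)
  # disjoint sets: empty cnvd
  cn <- intersect_sets(c("a", "b"), c("hz"), map)
  expect_length(cn$cnvd, 0)
  # unmapped sc features are treated as non-overlapping, with a message
  expect_message(cn2 <- intersect_sets(c("a", "zz"), c("ha"), map), "without")
  expect_equal(cn2$cnvd, "a")
  set.seed(18)
  for (i in 1:10) {
    sc <- sample(letters, sample(1:10, 1))
    fs <- sample(paste0("h", letters), sample(1:10, 1))
    m <- data.frame(query = letters, target = paste0("h", letters))
    cn3 <- suppressMessages(intersect_sets(sc, fs, m))
    expect_lte(length(cn3$cnvd), min(length(sc), length(fs)))
  }
  expect_error(intersect_sets(c("a"), c("ha")), "map")
})
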