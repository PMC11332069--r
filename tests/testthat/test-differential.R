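# differential: t-tests, fold changes, tiers, pair gating, pooled tests,
# Wilcoxon rank-sum

test_that("one-tailed t-test: null symmetry, scale invariance, reference oracle", {
  r <- one_tailed_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 0.5)
  expect_identical(r$direction, "none")

  x <- c(10, 11, 12); y <- c(1, 2, 3)
  r2 <- one_tailed_ttest(x, y)
  ref <- stats::t.test(x, y, alternative = "greater")  # independent Welch
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-12)
  expect_identical(r2$direction, "up_in_positive")

  r3 <- one_tailed_ttest(2 * x, 2 * y)
  expect_equal(r3$p_value, r2$p_value, tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:20) {
    a <- rnorm(5, 1); b <- rnorm(6)
    mine <- one_tailed_ttest(a, b)
    alt <- if (mean(a) >= mean(b)) "greater" else "less"
    expect_equal(mine$p_value, stats::t.test(a, b, alternative = alt)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("fixed tail modes and Student variant match stats::t.test", {
  set.seed(32)
  a <- rnorm(5); b <- rnorm(5, 0.5)
  expect_equal(one_tailed_ttest(a, b, tail_mode = "greater")$p_value,
               stats::t.test(a, b, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(one_tailed_ttest(a, b, tail_mode = "less")$p_value,
               stats::t.test(a, b, alternative = "less")$p.value,
               tolerance = 1e-12)
  expect_equal(one_tailed_ttest(a, b, tail_mode = "greater",
                                var_equal = TRUE)$p_value,
               stats::t.test(a, b, alternative = "greater",
                             var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("too few values flags the result untested", {
  r <- one_tailed_ttest(c(1, 2), c(1, 2, 3))
  expect_false(r$tested)
  expect_true(is.na(r$p_value))
})

test_that("two-tailed p is twice the observed-direction one-tailed p", {
  expect_equal(two_tailed_ttest(c(1, 2, 3), c(1, 2, 3)), 1.0)
  set.seed(33)
  for (rep in 1:10) {
    a <- rnorm(5); b <- rnorm(4, 0.3)
    expect_equal(two_tailed_ttest(a, b),
                 2 * one_tailed_ttest(a, b)$p_value, tolerance = 1e-12)
    expect_equal(two_tailed_ttest(a, b), stats::t.test(a, b)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("log2 fold change of group means", {
  expect_equal(log2_fold_change(c(8, 8), c(2, 2)), 2.0)
  expect_equal(log2_fold_change(c(3, 5), c(4, 4)), 0.0)
  expect_true(is.na(log2_fold_change(c(0, 0), c(1, 2))))
  set.seed(34)
  for (rep in 1:10) {
    a <- rlnorm(5); b <- rlnorm(5)
    expect_equal(log2_fold_change(a, b),
                 log2((sum(a) / 5) / (sum(b) / 5)), tolerance = 1e-12)
  }
})

test_that("significance tiers: significant / borderline / not / untested", {
  cfg <- analysis_config()
  expect_identical(classify_tier(c(0.04, 0.055, 0.2, NA), cfg),
                   c("significant", "borderline", "not_significant",
                     "untested"))
  # boundaries: alpha itself is borderline, borderline_hi is not
  expect_identical(classify_tier(c(0.05, 0.06), cfg),
                   c("borderline", "not_significant"))
})

test_that("pair gate requires full significance in at least one form", {
  res <- data.frame(feature_id = c("A", "B", "C", "D", "E", "F"),
                    tier = c("significant", "not_significant",
                             "not_significant", "not_significant",
                             "borderline", "not_significant"))
  pairs <- data.frame(feature_a = c("A", "C", "E"),
                      feature_b = c("B", "D", "F"))
  g <- gate_pairs(pairs, res)
  expect_identical(g$gate_passed, c(TRUE, FALSE, FALSE))
  expect_error(gate_pairs(data.frame(feature_a = "Z", feature_b = "A"), res),
               "'Z'")
})

test_that("pooled E1+E2 test equals testing the manually summed row", {
  set.seed(35)
  ints <- matrix(rlnorm(2 * 10, 10, 0.5), 2, 10)
  ft <- toy_table(ints, mz = c(304.1034, 304.1042), rt = c(10, 11.5),
                  groups = rep(c("positive", "negative"), each = 5))
  pair <- data.frame(e1 = "F001", e2 = "F002")
  got <- pooled_test(pair, ft)
  summed <- colSums(ints)
  # default config tests on the log2 scale
  manual <- one_tailed_ttest(log2(summed[1:5]), log2(summed[6:10]))
  expect_equal(got$p_value, manual$p_value, tolerance = 1e-12)
  expect_equal(got$log2_fc, log2_fold_change(summed[1:5], summed[6:10]),
               tolerance = 1e-12)
  expect_false(got$pool_fallback)

  # identical members: pooled log2 FC equals the member's
  ft2 <- toy_table(rbind(ints[1, ], ints[1, ]),
                   mz = c(304.1034, 304.1042), rt = c(10, 11.5),
                   groups = rep(c("positive", "negative"), each = 5))
  got2 <- pooled_test(pair, ft2)
  expect_equal(got2$log2_fc,
               log2_fold_change(ints[1, 1:5], ints[1, 6:10]),
               tolerance = 1e-12)

  # one member entirely missing: falls back to the other, flagged
  ints3 <- ints; ints3[2, ] <- NA
  ft3 <- toy_table(ints3, mz = c(304.1034, 304.1042), rt = c(10, 11.5),
                   groups = rep(c("positive", "negative"), each = 5))
  got3 <- pooled_test(pair, ft3)
  expect_true(got3$pool_fallback)
  expect_equal(got3$p_value,
               one_tailed_ttest(log2(ints[1, 1:5]),
                                log2(ints[1, 6:10]))$p_value,
               tolerance = 1e-12)
})

test_that("exact Wilcoxon matches enumeration; identical groups give p = 1", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$p_two_sided, 1 / 3, tolerance = 1e-12)  # 2 x 1/6

  r_id <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r_id$p_two_sided, 1.0)

  set.seed(36)
  for (rep in 1:10) {
    x <- sample(1:1000, 5); y <- sample(1001:2000, 5) - 1000.5
    r5 <- wilcoxon_rank_sum(x, y)
    expect_true(r5$exact)
    expect_equal(r5$p_two_sided, oracle_wilcoxon_enum(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("differential_test composes test, FC and tier per feature", {
  set.seed(37)
  ints <- matrix(rlnorm(20 * 10, 12, 0.5), 20, 10)
  ints[1, 1:4] <- NA  # only 1 positive value -> untested
  ints[1, 5] <- NA
  ft <- toy_table(ints, mz = 100 + seq_len(20), rt = seq_len(20) / 2,
                  groups = rep(c("positive", "negative"), each = 5))
  res <- differential_test(ft)
  expect_equal(nrow(res), 20L)
  expect_identical(res$tier[1], "untested")
  i <- 5L
  direct <- one_tailed_ttest(log2(ints[i, 1:5]), log2(ints[i, 6:10]))
  expect_equal(res$p_value[i], direct$p_value, tolerance = 1e-12)
  # raw-scale testing remains available
  res_raw <- differential_test(ft, analysis_config(test_on_log = FALSE))
  direct_raw <- one_tailed_ttest(ints[i, 1:5], ints[i, 6:10])
  expect_equal(res_raw$p_value[i], direct_raw$p_value, tolerance = 1e-12)
  expect_equal(res$log2_fc[i],
               log2_fold_change(ints[i, 1:5], ints[i, 6:10]),
               tolerance = 1e-12)
})
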