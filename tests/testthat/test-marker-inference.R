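# Detection power, exact intervals, G-tests and the preferential pairing
# estimator.

test_that("apparent heterozygosity pools counts across markers", {
  expect_equal(round(apparent_heterozygosity(326, 336), 2), 0.97)
  expect_equal(round(apparent_heterozygosity(332, 336), 2), 0.99)
  bc <- bc1n_counts()
  expect_equal(apparent_heterozygosity(bc$n_scored - bc$n_loss, bc$n_scored),
               326 / 336)
  expect_equal(apparent_heterozygosity(10, 10), 1)
  expect_error(apparent_heterozygosity(1, 0), "positive")
})

test_that("failure-to-detect probability follows (1 - q)^n", {
  expect_equal(prob_fail_to_detect("random-chromosome", "self", 309),
               (17 / 18)^309, tolerance = 1e-12)
  expect_equal(prob_fail_to_detect("random-chromosome", "self", 309),
               2.14e-8, tolerance = 0.005)
  expect_equal(prob_fail_to_detect("random-chromosome", "self", 308),
               2.26e-8, tolerance = 0.005)
  expect_equal(prob_fail_to_detect("random-chromosome", "self", 24),
               0.25, tolerance = 0.02)
  expect_equal(prob_fail_to_detect("random-chromosome", "backcross", 48),
               (5 / 6)^48, tolerance = 1e-12)
  expect_equal(prob_fail_to_detect("random-chromosome", "backcross", 336),
               2.48e-27, tolerance = 0.005)
  expect_equal(prob_fail_to_detect("max-equational", "self", 0), 1)
  # strictly decreasing in n and in the homozygote frequency q
  ns <- c(1, 10, 48, 100, 336)
  expect_true(all(diff(sapply(ns, function(n)
    prob_fail_to_detect("random-chromosome", "backcross", n))) < 0))
  q_order <- c("homolog-disomic", "random-chromosome", "random-chromatid",
               "max-equational", "homeolog-disomic")  # increasing q
  pf <- sapply(q_order, function(m) prob_fail_to_detect(m, "self", 48))
  expect_true(all(diff(pf) < 0))
})

test_that("Clopper-Pearson intervals match closed forms and stay exact", {
  ci <- clopper_pearson_ci(48, 48)
  expect_equal(ci$lower, 0.025^(1 / 48), tolerance = 1e-12)
  expect_equal(round(ci$lower, 3), 0.926)
  expect_identical(ci$upper, 1)
  ci2 <- clopper_pearson_ci(326, 336)
  expect_equal(round(ci2$lower, 3), 0.946)
  expect_equal(round(ci2$upper, 3), 0.986)
  # k = 0 is the mirror image of k = n
  ci0 <- clopper_pearson_ci(0, 48)
  expect_identical(ci0$lower, 0)
  expect_equal(ci0$upper, 1 - 0.025^(1 / 48), tolerance = 1e-12)
  expect_true(ci2$lower <= ci2$estimate && ci2$estimate <= ci2$upper)
  expect_error(clopper_pearson_ci(5, 0), "positive")
  expect_error(clopper_pearson_ci(5, 4), "k must lie")
})

test_that("Clopper-Pearson empirical coverage is at least nominal", {
  set.seed(481)
  n <- 48L
  for (p in c(0.8, 0.95, 0.99)) {
    k <- rbinom(1000L, n, p)
    covered <- vapply(k, function(ki) {
      ci <- clopper_pearson_ci(ki, n)
      ci$lower <= p && p <= ci$upper
    }, logical(1L))
    expect_gte(mean(covered), 0.93)
  }
})

test_that("G-test with Williams correction reproduces the pooled screen", {
  gt <- gtest_goodness_of_fit(c(326, 10), c(5 / 6, 1 / 6))
  expect_equal(gt$G, 2 * (326 * log(326 / 280) + 10 * log(10 / 56)),
               tolerance = 1e-12)
  expect_equal(gt$G, 64.72, tolerance = 1e-4)
  expect_equal(gt$q_williams, 1 + 3 / (6 * 336), tolerance = 1e-12)
  expect_equal(gt$G_adj, gt$G / gt$q_williams)
  expect_equal(gt$p_value, 9.07e-16, tolerance = 0.01)
  # observed proportional to expected
  gt0 <- gtest_goodness_of_fit(c(280, 56), c(5 / 6, 1 / 6))
  expect_equal(gt0$G, 0, tolerance = 1e-12)
  expect_equal(gt0$p_value, 1)
  # zero expected with nonzero observed is degenerate, not an error
  gtd <- gtest_goodness_of_fit(c(5, 1), c(1, 0))
  expect_true(gtd$degenerate)
  expect_true(is.na(gtd$p_value))
  expect_error(gtest_goodness_of_fit(c(5), c(1)), "classes")
  expect_error(gtest_goodness_of_fit(c(5, 5), c(0.6, 0.6)), "sum to 1")
})

test_that("chi-square tail agrees with numerical integration at df = 1", {
  for (g in c(0.5, 3.84, 10, 30)) {
    expect_equal(pchisq(g, 1, lower.tail = FALSE), chisq1_tail_numeric(g),
                 tolerance = 1e-8)
  }
})

test_that("heterogeneity G-test detects (only) real heterogeneity", {
  bc <- bc1n_counts()
  loss_markers <- bc[bc$n_loss > 0, ]
  gh <- heterogeneity_gtest(cbind(het = loss_markers$n_scored - loss_markers$n_loss,
                                  loss = loss_markers$n_loss))
  expect_equal(gh$G_adj, 1.99, tolerance = 0.005)
  expect_identical(gh$df, 5L)
  expect_equal(gh$p_value, 0.85, tolerance = 0.005)
  # identical proportions across markers: exactly homogeneous
  gh0 <- heterogeneity_gtest(cbind(c(45, 90), c(3, 6)))
  expect_equal(gh0$G, 0, tolerance = 1e-12)
  # additive decomposition: G_H = sum of per-marker G - pooled G, computed
  # against any common extrinsic ratio
  m <- cbind(het = c(40, 47), loss = c(8, 1))
  probs <- c(5 / 6, 1 / 6)
  g_i <- sapply(1:2, function(i)
    gtest_goodness_of_fit(m[i, ], probs, williams = FALSE)$G)
  g_pooled <- gtest_goodness_of_fit(colSums(m), probs, williams = FALSE)$G
  expect_equal(heterogeneity_gtest(m)$G, sum(g_i) - g_pooled,
               tolerance = 1e-10)
  expect_error(heterogeneity_gtest(m[1, , drop = FALSE]), ">= 2 markers")
})

test_that("preferential pairing estimates match the quadratic solution", {
  expect_equal(estimate_preferential_pairing(48, 2)$p_hat,
               (-4 + sqrt(52)) / 6, tolerance = 1e-12)
  expect_equal(round(estimate_preferential_pairing(48, 2)$p_hat, 2), 0.54)
  expect_equal(round(estimate_preferential_pairing(48, 3)$p_hat, 2), 0.46)
  expect_equal(round(estimate_preferential_pairing(48, 1)$p_hat, 2), 0.60)
  expect_identical(estimate_preferential_pairing(48, 0)$p_hat, 2 / 3)
  # strictly decreasing in the loss count; 2/3 iff no loss; the root leaves
  # [0, 2/3] once fewer than two-thirds of gametes are GN
  p_hats <- sapply(0:8, function(l) estimate_preferential_pairing(48, l)$p_hat)
  expect_true(all(diff(p_hats) < 0))
  expect_true(all(p_hats[-1L] < 2 / 3))
  expect_true(is.na(estimate_preferential_pairing(48, 9)$p_hat))
  expect_error(estimate_preferential_pairing(48, 25), "n_scored/2")
  # forward/backward consistency
  for (l in 0:8) {
    e <- estimate_preferential_pairing(48, l)
    expect_equal(wu_gn_frequency(e$p_hat, 0), e$f_gn_obs, tolerance = 1e-9)
  }
})

test_that("likelihood ratio test handles the degenerate strict-pairing null", {
  e0 <- estimate_preferential_pairing(48, 0)
  r0 <- lrt_preferential_pairing(e0, null_p = 2 / 3)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # any observed loss has probability zero under p = 2/3
  e1 <- estimate_preferential_pairing(48, 1)
  r1 <- lrt_preferential_pairing(e1)
  expect_true(r1$degenerate)
  expect_true(is.na(r1$p_value))
  # against an interior null: direct multinomial likelihood oracle
  e2 <- estimate_preferential_pairing(48, 2)
  r2 <- lrt_preferential_pairing(e2, null_p = 0.60)
  loglik <- function(f) 44 * log(f) + 4 * log((1 - f) / 2)
  expect_equal(r2$statistic,
               2 * (loglik(44 / 48) - loglik(wu_gn_frequency(0.60))),
               tolerance = 1e-10)
  expect_gt(r2$statistic, 0)
  expect_false(r2$degenerate)
})

test_that("panel reader validates schema and counts row by row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tarm_label\tclass\tn_scored\tn_het\tn_loss",
               "M1\t1L\tBC1N\t48\t46\t2",
               "M2\t2L\tBC1N\t48\t47\t5"), path)
  expect_error(read_marker_panel(path), "row 2.*M2")
  writeLines(c("marker_id\tclass\tn_scored", "M1\tBC1N\t48"), path)
  expect_error(read_marker_panel(path), "lacks column")
  writeLines(c("marker_id\tarm_label\tclass\tn_scored\tn_het\tn_loss",
               "M1\t1L\tBC1N\t48\t46\t2"), path)
  panel <- read_marker_panel(path)
  expect_s3_class(panel, "marker_panel")
  expect_identical(panel$n_loss_excl, panel$n_loss)
})
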