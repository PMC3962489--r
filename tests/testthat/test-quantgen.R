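# Variance-homogeneity tests, CV intervals, heritability, nested components.

test_that("variance ratio test matches the F distribution", {
  # samples scaled to the flowering-time variances 3.000 and 17.080
  set.seed(21)
  base <- scale(rnorm(30))[, 1]
  a <- base * sqrt(3.000)
  b <- scale(rnorm(40))[, 1] * sqrt(17.080)
  vt <- variance_ratio_test(a, b)
  expect_equal(vt$statistic, 17.080 / 3.000, tolerance = 1e-10)
  expect_equal(vt$statistic, 5.693, tolerance = 1e-3)
  expect_identical(vt$df, c(39L, 29L))
  # identical samples
  expect_equal(variance_ratio_test(a, a)$statistic, 1)
  expect_equal(variance_ratio_test(a, a)$p_value, 1, tolerance = 1e-12)
  # two-sided p against numerical integration of the F density
  dens_tail <- integrate(function(x) df(x, vt$df[1], vt$df[2]),
                         vt$statistic, Inf, rel.tol = 1e-10)$value
  expect_equal(vt$p_value, 2 * dens_tail, tolerance = 1e-8)
  # location invariance
  expect_equal(variance_ratio_test(a + 100, b + 7)$statistic, vt$statistic)
  expect_error(variance_ratio_test(rep(1, 5), a), "zero variance")
})

test_that("Levene test equals the ANOVA-on-deviations oracle", {
  g1 <- c(1, 3, 5, 9, 10)
  g2 <- c(2, 2.5, 3, 3.5, 4)
  lt <- levene_test(list(g1, g2))
  # manual Brown-Forsythe computation
  d <- c(abs(g1 - median(g1)), abs(g2 - median(g2)))
  grp <- rep(1:2, each = 5)
  msb <- sum(tapply(d, grp, function(x) length(x) * (mean(x) - mean(d))^2))
  msw <- sum((d - ave(d, grp))^2) / 8
  expect_equal(lt$statistic, msb / msw, tolerance = 1e-10)
  expect_equal(lt$p_value, pf(msb / msw, 1, 8, lower.tail = FALSE),
               tolerance = 1e-10)
  # independent implementation cross-check
  cl <- car::leveneTest(c(g1, g2), factor(grp), center = median)
  expect_equal(lt$statistic, cl$`F value`[1], tolerance = 1e-10)
  expect_equal(lt$p_value, cl$`Pr(>F)`[1], tolerance = 1e-10)
  # identical groups: no dispersion difference
  lt0 <- levene_test(list(g1, g1))
  expect_equal(lt0$statistic, 0)
  expect_equal(lt0$p_value, 1)
  # median-centered version is invariant to per-group location shifts
  lt_shift <- levene_test(list(g1 + 50, g2 - 3))
  expect_equal(lt_shift$statistic, lt$statistic, tolerance = 1e-10)
  expect_error(levene_test(list(g1)), ">= 2 groups")
})

test_that("Levene test has power against a fourfold variance difference", {
  set.seed(22)
  hits <- replicate(200, {
    x <- rnorm(200, sd = 1)
    y <- rnorm(200, sd = 2)
    levene_test(list(x, y))$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("CV interval behaves under scaling and large n", {
  x <- c(8, 9, 10, 11, 12)
  cv <- cv_with_ci(x)
  expect_equal(cv$cv, 100 * sd(x) / mean(x), tolerance = 1e-12)
  expect_equal(cv$cv_corrected, (1 + 1 / 20) * cv$cv, tolerance = 1e-12)
  expect_true(cv$lower < cv$cv_corrected && cv$cv_corrected < cv$upper)
  # scale invariance and zero-dispersion edge
  expect_equal(cv_with_ci(2 * x)$cv, cv$cv, tolerance = 1e-12)
  expect_equal(cv_with_ci(rep(4, 10))$cv, 0)
  # correction factor tends to 1
  set.seed(23)
  big <- rnorm(1e5, mean = 50, sd = 5)
  big_cv <- cv_with_ci(big)
  expect_equal(big_cv$cv_corrected / big_cv$cv, 1, tolerance = 1e-4)
  expect_error(cv_with_ci(c(-5, -4, -6)), "non-positive mean")
})

test_that("broad-sense heritability arithmetic and invariances", {
  expect_equal(broad_sense_heritability(2, 0.5, 0.5, 0.5)$h2_broad, 0.75)
  h <- broad_sense_heritability(17.080, var_f1 = 4.782, var_p1 = 4.782,
                                var_p2 = 4.782)
  expect_equal(h$var_e, 4.782)
  expect_equal(h$h2_broad, 0.72, tolerance = 0.005)
  # V_E = V_P: no genetic variance; negative values pass through
  expect_equal(broad_sense_heritability(1, 1, 1, 1)$h2_broad, 0)
  expect_lt(broad_sense_heritability(1, 2, 2, 2)$h2_broad, 0)
  # scale invariance
  h1 <- broad_sense_heritability(10, 2, 3, 1)
  h2 <- broad_sense_heritability(10 * 7, 2 * 7, 3 * 7, 1 * 7)
  expect_equal(h1$h2_broad, h2$h2_broad, tolerance = 1e-12)
  # weighting options
  expect_equal(broad_sense_heritability(10, 1, 2, 3, "weighted")$var_e, 7 / 4)
  expect_equal(broad_sense_heritability(10, 1, 2, 3, "mean3")$var_e, 2)
})

test_that("nested variance components recover the generating model", {
  # percent-of-total arithmetic as reported for the flowering-time family
  # component: 10.64 of a 47.61 total
  expect_equal(round(100 * 10.64 / 47.61, 2), 22.35)

  set.seed(24)
  d <- make_nested_data(30, 2, 3, s2_fam = 4, s2_mat = 1, s2_res = 2)
  vc <- nested_variance_components(d)
  expect_named(vc$components,
               c("family", "maternal_within_family", "residual"))
  expect_equal(sum(vc$pct_total), 100, tolerance = 0.1)
  expect_true(all(vc$se > 0))
  # balanced design with interior estimates: REML (lme4) agrees with EMS
  fit <- lme4::lmer(trait ~ 1 + (1 | family / maternal_line), data = d,
                    REML = TRUE)
  vc_reml <- as.data.frame(lme4::VarCorr(fit))
  reml <- c(family = vc_reml$vcov[vc_reml$grp == "family"],
            maternal = vc_reml$vcov[vc_reml$grp == "maternal_line:family"],
            residual = vc_reml$vcov[vc_reml$grp == "Residual"])
  expect_equal(unname(vc$components), unname(reml), tolerance = 1e-4)
  # degenerate designs are rejected
  expect_error(nested_variance_components(d[d$family == 1, ]), "2 families")
  one_line <- make_nested_data(5, 2, 3, 1, 1, 1)
  one_line$maternal_line <- 1
  expect_error(nested_variance_components(one_line), "2 maternal lines")
})

test_that("null family variance is estimated near zero on average", {
  set.seed(25)
  ests <- replicate(100, {
    d <- make_nested_data(20, 2, 3, s2_fam = 0, s2_mat = 1, s2_res = 2)
    nested_variance_components(d)$components[["family"]]
  })
  expect_lt(abs(mean(ests)), 2 * sd(ests) / sqrt(length(ests)))
})

test_that("negative component estimates are reported but floored in percents", {
  set.seed(26)
  # tiny maternal variance invites negative maternal estimates; find one
  found <- FALSE
  for (i in 1:50) {
    d <- make_nested_data(10, 2, 2, s2_fam = 1, s2_mat = 0, s2_res = 3)
    vc <- nested_variance_components(d)
    if (vc$components[["maternal_within_family"]] < 0) {
      found <- TRUE
      expect_identical(vc$pct_total[["maternal_within_family"]], 0)
      expect_equal(sum(vc$pct_total), 100, tolerance = 1e-9)
      break
    }
  }
  expect_true(found)
})
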