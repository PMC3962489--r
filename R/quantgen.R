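#' Two-sample variance ratio (F) test
#'
#' Tests whether the second sample (typically a segregating F2) is more
#' variable than the first (typically the F1): `F = var(b)/var(a)` with
#' `(n_b - 1, n_a - 1)` degrees of freedom and a two-sided p-value
#' `2 * min(tail, 1 - tail)`.
#'
#' @param sample_a,sample_b Numeric vectors with at least 2 values each.
#' @return List of class `"variance_test"`: `statistic`, `df` (length 2),
#'   `p_value`, `method = "F_RATIO"`.
#' @examples
#' variance_ratio_test(rnorm(30), rnorm(30, sd = 2))
#' @export
variance_ratio_test <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs >= 2 finite values", call. = FALSE)
  va <- stats::var(sample_a)
  if (va == 0) stop("zero variance in denominator sample", call. = FALSE)
  f <- stats::var(sample_b) / va
  df <- c(length(sample_b) - 1L, length(sample_a) - 1L)
  tail <- stats::pf(f, df[1L], df[2L])
  structure(list(statistic = f, df = df,
                 p_value = min(1, 2 * min(tail, 1 - tail)),
                 method = "F_RATIO"),
            class = "variance_test")
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group center. The default
#' center is the group median (the Brown-Forsythe variant), which is
#' robust to asymmetric trait distributions; mean-centering gives the
#' classical Levene statistic.
#'
#' @param values Numeric vector of observations.
#' @param group Group labels (coerced to factor), or `values` may be a
#'   list of numeric vectors with `group` missing.
#' @param center `"median"` (default) or `"mean"`.
#' @return List of class `"variance_test"`: `statistic` (the ANOVA F),
#'   `df`, `p_value`, `method` (`"LEVENE_MEDIAN"` or `"LEVENE_MEAN"`).
#' @examples
#' levene_test(list(rnorm(30), rnorm(30, sd = 2)))
#' @export
levene_test <- function(values, group, center = c("median", "mean")) {
  center <- match.arg(center)
  if (is.list(values) && missing(group)) {
    group <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(group) < 2L)) stop("every group needs >= 2 values", call. = FALSE)
  cfun <- if (center == "median") stats::median else mean
  centers <- tapply(values, group, cfun)
  dev <- abs(values - centers[group])
  fit <- stats::anova(stats::aov(dev ~ group))
  structure(list(statistic = fit$`F value`[1L],
                 df = fit$Df,
                 p_value = fit$`Pr(>F)`[1L],
                 method = paste0("LEVENE_", toupper(center))),
            class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$method, x$statistic, paste(x$df, collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Coefficient of variation with confidence interval
#'
#' `CV = 100 s / mean`, corrected for small samples as
#' `CV* = (1 + 1/(4n)) CV`, with normal-approximation interval
#' `CV* +/- z * CV* * sqrt(1 / (2(n - 1)))`.
#'
#' @param sample Numeric vector with positive mean and `n >= 2`.
#' @param conf Confidence level (default 0.95).
#' @return List of class `"cv_result"`: `cv`, `cv_corrected`, `lower`,
#'   `upper`, `n`.
#' @examples
#' cv_with_ci(rnorm(50, mean = 10))
#' @export
cv_with_ci <- function(sample, conf = 0.95) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  m <- mean(sample)
  if (m <= 0)
    stop("CV undefined for non-positive mean (", signif(m, 4), ")",
         call. = FALSE)
  cv <- 100 * stats::sd(sample) / m
  cv_star <- (1 + 1 / (4 * n)) * cv
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * cv_star * sqrt(1 / (2 * (n - 1)))
  structure(list(cv = cv, cv_corrected = cv_star,
                 lower = cv_star - half, upper = cv_star + half, n = n),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV = %.3f%%, corrected CV* = %.3f%% [%.3f, %.3f] (n = %d)\n",
              x$cv, x$cv_corrected, x$lower, x$upper, x$n))
  invisible(x)
}

#' Broad-sense heritability from F2 segregational variance
#'
#' \eqn{H^2 = V_G / V_P} with \eqn{V_G = Var(F_2) - V_E} and \eqn{V_P =
#' Var(F_2)}. The environmental variance is estimated from the
#' non-segregating classes: by default the weighted form
#' \eqn{V_E = (V_{P1} + V_{P2} + 2 V_{F1}) / 4}, alternatively the
#' unweighted mean of the three variances. Negative estimates are returned
#' unmodified — they indicate an absence of segregational variance, not an
#' error.
#'
#' @param var_f2 Phenotypic variance of the F2 (> 0).
#' @param var_f1,var_p1,var_p2 Variances of the F1 and the two parental
#'   lines.
#' @param ve_method `"weighted"` (default) or `"mean3"`.
#' @return List of class `"heritability"`: `var_f2`, `var_e`, `var_g`,
#'   `h2_broad`, `ve_method`.
#' @examples
#' broad_sense_heritability(17.08, var_f1 = 3.0, var_p1 = 5.3, var_p2 = 0.9)
#' @export
broad_sense_heritability <- function(var_f2, var_f1, var_p1, var_p2,
                                     ve_method = c("weighted", "mean3")) {
  ve_method <- match.arg(ve_method)
  if (!is.finite(var_f2) || var_f2 <= 0)
    stop("var_f2 must be positive", call. = FALSE)
  var_e <- switch(ve_method,
                  weighted = (var_p1 + var_p2 + 2 * var_f1) / 4,
                  mean3 = (var_p1 + var_p2 + var_f1) / 3)
  var_g <- var_f2 - var_e
  structure(list(var_f2 = var_f2, var_e = var_e, var_g = var_g,
                 h2_broad = var_g / var_f2, ve_method = ve_method),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("H^2 = %.3f  (V_P = %.4g, V_E = %.4g [%s], V_G = %.4g)\n",
              x$h2_broad, x$var_f2, x$var_e, x$ve_method, x$var_g))
  invisible(x)
}

#' Nested variance components by expected mean squares
#'
#' Method-of-moments estimators for the two-level nested random-effects
#' model (families, maternal lines nested within families, residual),
#' using the unbalanced-design expected-mean-square coefficients of the
#' classical nested ANOVA. Component estimates may be negative and are
#' reported as such; for the percent-of-total column negative components
#' are floored at zero before forming percentages, which therefore sum to
#' 100. Approximate standard errors come from the large-sample variance of
#' the mean squares, \eqn{Var(MS) = 2 MS^2 / df}, propagated through the
#' linear estimators.
#'
#' @param records Data frame with columns `family`, `maternal_line` and
#'   the trait column.
#' @param trait Name of the trait column (default `"trait"`).
#' @return List of class `"nested_varcomp"` with `components` (named
#'   vector: family, maternal_within_family, residual), `se`, `pct_total`,
#'   `total` and the mean squares.
#' @examples
#' d <- expand.grid(family = 1:8, maternal_line = 1:2, rep = 1:3)
#' d$trait <- rnorm(8, sd = 2)[d$family] + rnorm(nrow(d))
#' nested_variance_components(d)
#' @export
nested_variance_components <- function(records, trait = "trait") {
  need <- c("family", "maternal_line", trait)
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  y <- records[[trait]]
  fam <- factor(records$family)
  mat <- factor(paste(records$family, records$maternal_line))
  a <- nlevels(fam)
  if (a < 2L) stop("need >= 2 families", call. = FALSE)
  b_per <- tapply(as.character(mat), fam, function(x) length(unique(x)))
  if (any(b_per < 2L))
    stop("need >= 2 maternal lines in every family", call. = FALSE)
  n_ij <- table(mat)
  if (any(n_ij < 2L))
    stop("need >= 2 individuals in every maternal line", call. = FALSE)
  N <- length(y)
  n_i <- as.numeric(table(fam))
  grand <- mean(y)
  fam_mean <- tapply(y, fam, mean)
  mat_mean <- tapply(y, mat, mean)
  fam_of_mat <- tapply(as.character(fam), mat, `[`, 1L)

  ss_fam <- sum(n_i * (fam_mean - grand)^2)
  ss_mat <- sum(as.numeric(n_ij) * (mat_mean - fam_mean[fam_of_mat])^2)
  ss_res <- sum((y - mat_mean[mat])^2)
  df_fam <- a - 1L
  df_mat <- sum(b_per - 1L)
  df_res <- N - nlevels(mat)
  ms <- c(fam = ss_fam / df_fam, mat = ss_mat / df_mat, res = ss_res / df_res)

  # unbalanced EMS coefficients
  nij2_by_fam <- tapply(as.numeric(n_ij)^2, fam_of_mat, sum)
  sum_nij2_over_ni <- sum(nij2_by_fam / n_i[match(names(nij2_by_fam), levels(fam))])
  n0_sub <- (N - sum_nij2_over_ni) / df_mat              # E[MS_mat] = s2 + n0_sub * s2_mat
  c1 <- (sum_nij2_over_ni - sum(as.numeric(n_ij)^2) / N) / df_fam
  c2 <- (N - sum(n_i^2) / N) / df_fam                    # E[MS_fam] = s2 + c1 s2_mat + c2 s2_fam

  s2_res <- ms[["res"]]
  s2_mat <- (ms[["mat"]] - s2_res) / n0_sub
  s2_fam <- (ms[["fam"]] - s2_res - c1 * s2_mat) / c2
  comp <- c(family = s2_fam, maternal_within_family = s2_mat,
            residual = s2_res)

  v_ms <- 2 * ms^2 / c(df_fam, df_mat, df_res)
  se <- sqrt(c(
    family = (v_ms[["fam"]] + (c1 / n0_sub)^2 * v_ms[["mat"]] +
                (1 - c1 / n0_sub)^2 * v_ms[["res"]]) / c2^2,
    maternal_within_family = (v_ms[["mat"]] + v_ms[["res"]]) / n0_sub^2,
    residual = v_ms[["res"]]))

  floored <- pmax(comp, 0)
  pct <- if (sum(floored) > 0) 100 * floored / sum(floored) else floored
  structure(list(components = comp, se = se, pct_total = pct,
                 total = sum(comp), mean_squares = ms,
                 df = c(df_fam, df_mat, df_res),
                 coefficients = c(n0_sub = n0_sub, c1 = c1, c2 = c2)),
            class = "nested_varcomp")
}

#' @export
print.nested_varcomp <- function(x, digits = 3L, ...) {
  out <- data.frame(component = names(x$components),
                    variance = round(x$components, digits),
                    se = round(x$se, digits),
                    pct_total = round(x$pct_total, 2L))
  print(out, row.names = FALSE)
  cat(sprintf("total = %.4g\n", x$total))
  invisible(x)
}
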