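#' Apparent heterozygosity of a marker or pooled panel
#'
#' Fraction of scored individuals showing a marker band from each parent.
#' Counts may be vectors (one entry per marker), in which case `pooled =
#' TRUE` sums counts across markers before dividing.
#'
#' @param n_het Number of apparently heterozygous individuals.
#' @param n_scored Number of individuals scored (> 0).
#' @param pooled Sum counts across entries before forming the proportion.
#' @return Proportion(s) in \eqn{[0, 1]}.
#' @examples
#' apparent_heterozygosity(326, 336)          # pooled backcross panel: 0.970
#' @export
apparent_heterozygosity <- function(n_het, n_scored, pooled = length(n_het) > 1L) {
  stopifnot(length(n_het) == length(n_scored))
  if (any(n_scored <= 0)) stop("n_scored must be positive", call. = FALSE)
  if (any(n_het < 0) || any(n_het > n_scored))
    stop("n_het must lie in [0, n_scored]", call. = FALSE)
  if (pooled) sum(n_het) / sum(n_scored) else n_het / n_scored
}

#' Probability of failing to detect non-homologous segregation
#'
#' Quadruple homozygotes (GGGG or NNNN) are the direct marker evidence of
#' non-homologous chromosome pairing. Given a pairing model and progeny
#' design, the per-individual quadruple-homozygote probability `q` is taken
#' from the model's progeny genotype distribution (both homozygous classes
#' under selfing, only the tester-homozygote class under backcrossing), and
#' the probability that `n_obs` independent progeny contain none is
#' \eqn{(1-q)^{n_{obs}}}.
#'
#' @param model Pairing model name (see [pairing_model()]).
#' @param design `"self"` or `"backcross"`.
#' @param n_obs Number of scored progeny (or marker-by-progeny
#'   combinations when pooling markers), \eqn{\ge 0}.
#' @return Probability of observing zero quadruple homozygotes.
#' @examples
#' prob_fail_to_detect("random-chromosome", "self", 309)     # ~2.14e-8
#' prob_fail_to_detect("random-chromosome", "backcross", 48) # ~1.58e-4
#' @export
prob_fail_to_detect <- function(model, design = c("self", "backcross"), n_obs) {
  design <- match.arg(design)
  if (length(n_obs) != 1L || !is.finite(n_obs) || n_obs < 0)
    stop("n_obs must be a single nonnegative count", call. = FALSE)
  g <- gamete_ratios(model)
  geno <- if (design == "self") progeny_genotype_frequencies(g)
          else progeny_genotype_frequencies(g, c(0, 0, 1))
  q <- if (design == "self") geno[[1L]] + geno[[5L]] else geno[[5L]]
  (1 - q)^n_obs
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact interval for a binomial proportion via beta quantiles: lower bound
#' `qbeta(a/2, k, n-k+1)`, upper `qbeta(1-a/2, k+1, n-k)`, with the closed
#' forms 0 and \eqn{(a/2)^{1/n}} at the boundaries `k = 0` and `k = n`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, > 0.
#' @param conf Confidence level in (0, 1); default 0.95.
#' @return A list of class `"binomial_ci"` with elements `k`, `n`,
#'   `estimate`, `conf`, `lower`, `upper`.
#' @examples
#' clopper_pearson_ci(48, 48)     # lower = 0.025^(1/48) = 0.926
#' clopper_pearson_ci(326, 336)   # 0.946 - 0.986
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  if (!is.finite(conf) || conf <= 0 || conf >= 1)
    stop("conf must lie in (0, 1)", call. = FALSE)
  a <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  structure(list(k = k, n = n, estimate = k / n, conf = conf,
                 lower = lower, upper = upper),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, digits = 3L, ...) {
  cat(sprintf("%d/%d = %.*f, %g%% exact CI [%.*f, %.*f]\n",
              x$k, x$n, digits, x$estimate, 100 * x$conf,
              digits, x$lower, digits, x$upper))
  invisible(x)
}

#' G-test (log-likelihood ratio) goodness of fit
#'
#' \eqn{G = 2 \sum o \ln(o/e)} against extrinsic expected class
#' probabilities, optionally divided by the Williams correction
#' \eqn{q = 1 + (a^2 - 1)/(6 n (a - 1))} for `a` classes and `n` total
#' observations; the p-value is the upper chi-square tail with `a - 1`
#' degrees of freedom.
#'
#' @param observed Nonnegative integer counts per class (length \eqn{\ge} 2).
#' @param expected_probs Expected class probabilities, summing to 1.
#' @param williams Apply the Williams correction (default `TRUE`).
#' @return Object of class `"gtest"`: list with `G`, `q_williams`, `G_adj`,
#'   `df`, `p_value`, `degenerate`. When an expected probability is zero
#'   with a nonzero observed count, `degenerate` is `TRUE` and the
#'   statistic and p-value are `NA`.
#' @examples
#' gtest_goodness_of_fit(c(326, 10), c(5/6, 1/6))   # p ~ 9.07e-16
#' @export
gtest_goodness_of_fit <- function(observed, expected_probs, williams = TRUE) {
  a <- length(observed)
  if (a < 2L || length(expected_probs) != a)
    stop("need >= 2 classes with matching expected probabilities", call. = FALSE)
  if (any(observed < 0) || sum(observed) <= 0)
    stop("observed counts must be nonnegative with positive total", call. = FALSE)
  if (abs(sum(expected_probs) - 1) > 1e-8)
    stop("expected probabilities must sum to 1", call. = FALSE)
  n <- sum(observed)
  if (any(expected_probs == 0 & observed > 0)) {
    return(structure(list(G = NA_real_, q_williams = NA_real_,
                          G_adj = NA_real_, df = a - 1L, p_value = NA_real_,
                          degenerate = TRUE),
                     class = "gtest"))
  }
  e <- n * expected_probs
  keep <- observed > 0
  G <- 2 * sum(observed[keep] * log(observed[keep] / e[keep]))
  q <- if (williams) 1 + (a^2 - 1) / (6 * n * (a - 1)) else 1
  G_adj <- G / q
  structure(list(G = G, q_williams = q, G_adj = G_adj, df = a - 1L,
                 p_value = stats::pchisq(G_adj, a - 1L, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "gtest")
}

#' @export
print.gtest <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("G-test: degenerate (expected count 0 with nonzero observation)\n")
  } else {
    cat(sprintf("G = %.4g, Williams q = %.6g, G_adj = %.4g, df = %d, p = %.3g\n",
                x$G, x$q_williams, x$G_adj, x$df, x$p_value))
  }
  invisible(x)
}

#' Heterogeneity G-test across replicated marker counts
#'
#' Tests whether per-marker heterozygous/loss proportions are homogeneous.
#' Expected counts for each marker come from the pooled proportion across
#' markers; \eqn{G_H = 2 \sum_{markers} \sum_{classes} o \ln(o/e)} with
#' \eqn{(m-1)(c-1)} degrees of freedom. This equals the decomposition
#' \eqn{\sum G_i - G_{pooled}} computed against any common extrinsic ratio.
#' No Williams correction is applied by default.
#'
#' @param counts A matrix of nonnegative counts, one row per marker and one
#'   column per class (e.g. heterozygous, loss), or a marker panel data
#'   frame with columns `n_het` and `n_loss`.
#' @param williams Apply the Williams correction to \eqn{G_H} (default
#'   `FALSE`).
#' @return Object of class `"gtest"` (see [gtest_goodness_of_fit()]).
#' @examples
#' m <- cbind(het = c(46, 47, 45, 47, 47, 46), loss = c(2, 1, 3, 1, 1, 2))
#' heterogeneity_gtest(m)    # G_H = 1.99, p = 0.85
#' @export
heterogeneity_gtest <- function(counts, williams = FALSE) {
  if (is.data.frame(counts)) {
    if (!all(c("n_het", "n_loss") %in% names(counts)))
      stop("panel data frame must have columns n_het and n_loss", call. = FALSE)
    counts <- cbind(het = counts$n_het, loss = counts$n_loss)
  }
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need >= 2 markers and >= 2 classes", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  row_n <- rowSums(counts)
  if (any(row_n == 0)) stop("every marker needs a positive total", call. = FALSE)
  col_p <- colSums(counts) / sum(counts)
  e <- outer(row_n, col_p)
  keep <- counts > 0
  G <- 2 * sum(counts[keep] * log(counts[keep] / e[keep]))
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  q <- if (williams) 1 + (nrow(counts) * ncol(counts) - 1) /
         (6 * sum(counts) * df) else 1
  structure(list(G = G, q_williams = q, G_adj = G / q, df = df,
                 p_value = stats::pchisq(G / q, df, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "gtest")
}

#' Estimate the preferential pairing factor from backcross marker counts
#'
#' In a backcross of the duplex F1 tetraploid to the quadruple-recessive
#' tester, progeny that have lost the dominant-parent band must have
#' received an NN gamete from the F1. Assuming the F1 produced equal
#' numbers of GG and NN gametes (GG gametes are invisible in the backcross),
#' the inferred gamete counts are `NN = n_loss`, `GG = n_loss`,
#' `GN = n_scored - 2 n_loss`, and the GN frequency is inverted for `p` via
#' [solve_pairing_factor()] under the chosen pairing assumption.
#'
#' @param n_scored Number of progeny scored at the marker.
#' @param n_loss Number of progeny homozygous for the tester allele
#'   (band loss); must not exceed `n_scored / 2`.
#' @param assumption `"bivalent"` or `"quadrivalent"` (see
#'   [solve_pairing_factor()]).
#' @return Object of class `"ppf_estimate"`: list with `p_hat`,
#'   `assumption`, `f_gn_obs`, and the inferred gamete counts `counts`
#'   (GN, GG, NN).
#' @examples
#' estimate_preferential_pairing(48, 2)    # p_hat = 0.535 (Table-style 0.54)
#' estimate_preferential_pairing(48, 0)    # p_hat = 2/3
#' @export
estimate_preferential_pairing <- function(n_scored, n_loss,
                                          assumption = c("bivalent", "quadrivalent")) {
  assumption <- match.arg(assumption)
  stopifnot(length(n_scored) == 1L, length(n_loss) == 1L)
  if (n_scored <= 0) stop("n_scored must be positive", call. = FALSE)
  if (n_loss < 0) stop("n_loss must be nonnegative", call. = FALSE)
  if (n_loss > n_scored / 2)
    stop("n_loss > n_scored/2: inferred GN count would be negative; ",
         "no preferential-pairing solution in range", call. = FALSE)
  counts <- c(GN = n_scored - 2 * n_loss, GG = n_loss, NN = n_loss)
  f_gn <- counts[["GN"]] / sum(counts)
  p_hat <- solve_pairing_factor(f_gn, assumption)
  structure(list(p_hat = as.numeric(p_hat), assumption = assumption,
                 f_gn_obs = f_gn, counts = counts,
                 na_reason = attr(p_hat, "reason")),
            class = "ppf_estimate")
}

#' @export
print.ppf_estimate <- function(x, ...) {
  cat(sprintf("preferential pairing factor p_hat = %.4f (%s assumption)\n",
              x$p_hat, x$assumption))
  cat(sprintf("  inferred gametes GN:GG:NN = %d:%d:%d (f_GN = %.4f)\n",
              x$counts[["GN"]], x$counts[["GG"]], x$counts[["NN"]], x$f_gn_obs))
  invisible(x)
}

#' @export
coef.ppf_estimate <- function(object, ...) c(p = object$p_hat)

#' Likelihood ratio test for the preferential pairing factor
#'
#' Multinomial likelihood ratio test of the inferred gamete counts (GN, GG,
#' NN) under class frequencies \eqn{\{f(p), (1-f(p))/2, (1-f(p))/2\}}
#' comparing the estimate `p_hat` against a null value. When the null is
#' `p = 2/3` (strict homologous pairing) and any loss was observed, the
#' null assigns probability zero to the data: the test is degenerate and no
#' finite p-value exists.
#'
#' @param est A `"ppf_estimate"` from [estimate_preferential_pairing()].
#' @param null_p Null value of the pairing factor (default `2/3`).
#' @return List with `statistic`, `df`, `p_value`, `degenerate`.
#' @examples
#' e <- estimate_preferential_pairing(48, 2)
#' lrt_preferential_pairing(e, null_p = 0.60)
#' lrt_preferential_pairing(e)                 # degenerate at null 2/3
#' @export
lrt_preferential_pairing <- function(est, null_p = 2 / 3) {
  stopifnot(inherits(est, "ppf_estimate"))
  check_wu_params(null_p, 0)
  counts <- est$counts
  loglik <- function(f_gn) {
    probs <- c(f_gn, (1 - f_gn) / 2, (1 - f_gn) / 2)
    if (any(probs == 0 & counts > 0)) return(-Inf)
    keep <- counts > 0
    sum(counts[keep] * log(probs[keep]))
  }
  f_null <- wu_gn_frequency(null_p, 0)
  l1 <- loglik(est$f_gn_obs)
  l0 <- loglik(f_null)
  if (!is.finite(l0)) {
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_,
                degenerate = TRUE))
  }
  stat <- 2 * (l1 - l0)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
       degenerate = FALSE)
}
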