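#' Gamete-class frequencies under the preferential-pairing model
#'
#' Single-locus gamete-class frequencies for a duplex allotetraploid
#' (G1G2N1N2) as a function of the preferential pairing factor `p` and the
#' double reduction rate `alpha`. `p` measures how often homologous
#' chromosomes pair rather than homeologs: `p = 0` is fully random pairing
#' and `p = 2/3` strict homologous bivalent formation (1/3 of bivalent
#' pairings are homologous at random, so strict pairing adds 2/3).
#'
#' `wu_gn_frequency()` returns the frequency of balanced GN gametes (one
#' allele from each subgenome),
#' \deqn{f_{GN}(p, \alpha) = 2/9 + p/3 + 5p^2/4 +
#'       (2/3)\,(2/3 - 3p^2/2 - \alpha(2/3 - 3p^2/2)),}
#' which at \eqn{\alpha = 0} simplifies to \eqn{2/3 + p/3 + p^2/4}.
#' `wu_dr_frequency()` returns the total frequency of double-reduction
#' gametes (both chromatids from one chromosome: G1G1, G2G2, N1N1, N2N2),
#' \eqn{\alpha\,(2/3 - 3p^2/2)}.
#'
#' @param p Preferential pairing factor, in \eqn{[0, 2/3]}.
#' @param alpha Double reduction rate, \eqn{\ge 0}; the double-reduction
#'   gamete frequency `alpha * (2/3 - 3/2 p^2)` must lie in \eqn{[0, 1]}.
#' @return A probability (vectorised over `p`). `wu_gn_frequency()` clamps
#'   to \eqn{[0, 1]} against floating-point overshoot at the boundary.
#' @examples
#' wu_gn_frequency(2/3)        # 1: fixed heterozygosity
#' wu_gn_frequency(0)          # 2/3: fully random bivalent pairing
#' @export
wu_gn_frequency <- function(p, alpha = 0) {
  check_wu_params(p, alpha)
  bracket <- 2 / 3 - 1.5 * p^2
  f <- 2 / 9 + p / 3 + 1.25 * p^2 + (2 / 3) * (bracket - alpha * bracket)
  pmin(pmax(f, 0), 1)
}

#' @rdname wu_gn_frequency
#' @export
wu_dr_frequency <- function(p, alpha = 0) {
  check_wu_params(p, alpha)
  alpha * (2 / 3 - 1.5 * p^2)
}

check_wu_params <- function(p, alpha) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 2 / 3 + 1e-12))
    stop("preferential pairing factor p must lie in [0, 2/3]", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("double reduction rate alpha must be >= 0", call. = FALSE)
  if (any(alpha * (2 / 3 - 1.5 * p^2) > 1))
    stop("alpha * (2/3 - 3/2 p^2) exceeds 1: not a valid gamete frequency",
         call. = FALSE)
  invisible(TRUE)
}

#' Solve the preferential pairing factor from an observed GN-gamete frequency
#'
#' Inverts the gamete-frequency model for `p` given the observed (or
#' inferred) frequency of balanced GN gametes. Under the bivalent-only
#' assumption the double-reduction term is zero and
#' \eqn{2/3 + p/3 + p^2/4 = f_{GN}} is solved for its positive root,
#' \eqn{p = (-4 + \sqrt{144 f_{GN} - 80})/6.}
#' Under the quadrivalent double-reduction assumption, 3/8 of all GG and NN
#' gametes are attributed to double reduction (the share expected when all
#' nine quadrivalent arrangement/separation combinations are equally
#' likely), which after substitution gives
#' \eqn{p = (-4 + \sqrt{108 f_{GN} - 44})/6.}
#'
#' @param f_gn Observed GN-gamete frequency, in \eqn{[0, 1]}.
#' @param assumption `"bivalent"` (all GG/NN gametes from homeologous
#'   bivalents; no double reduction) or `"quadrivalent"` (all GG/NN gametes
#'   from quadrivalents, with the 3/8 double-reduction share).
#' @return The estimate of `p`, clamped to \eqn{[0, 2/3]}; `NA_real_` when
#'   `f_gn` is too small for a root in range (attribute `"reason"` says
#'   why).
#' @examples
#' solve_pairing_factor(44/48)   # 0.535...: 2 of 48 backcross progeny lost a band
#' solve_pairing_factor(1)       # 2/3
#' @export
solve_pairing_factor <- function(f_gn, assumption = c("bivalent", "quadrivalent")) {
  assumption <- match.arg(assumption)
  if (!is.finite(f_gn) || f_gn < 0 || f_gn > 1 + 1e-12)
    stop("f_gn must be a frequency in [0, 1]", call. = FALSE)
  disc <- switch(assumption,
                 bivalent = 144 * f_gn - 80,
                 quadrivalent = 108 * f_gn - 44)
  if (disc < 0)
    return(structure(NA_real_, reason = "no root in [0, 2/3]: f_gn too small"))
  p <- (-4 + sqrt(disc)) / 6
  if (p < 0)
    return(structure(NA_real_, reason = "no root in [0, 2/3]: f_gn too small"))
  min(p, 2 / 3)
}
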