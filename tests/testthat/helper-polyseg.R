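# Shared fixtures built in code.

# Backcross rows of the bundled panel: 7 markers, 48 scored each.
bc1n_counts <- function() {
  data.frame(
    marker_id = c("MgSTS_98", "MgSTS_787", "MgSTS_724", "MgSTS_376",
                  "MgSTS_358", "MgSTS_780", "MgSTS_847"),
    n_scored = 48L,
    n_loss = c(2L, 1L, 3L, 0L, 1L, 1L, 2L),
    n_loss_excl = c(1L, 0L, 2L, 0L, 0L, 0L, 1L))
}

# Balanced two-level nested random-effects data: a families x b maternal
# lines x n individuals with the given variance components.
make_nested_data <- function(a, b, n, s2_fam, s2_mat, s2_res, mu = 10) {
  fam <- rep(seq_len(a), each = b * n)
  mat <- rep(rep(seq_len(b), each = n), times = a)
  data.frame(
    family = fam, maternal_line = mat,
    trait = mu + rnorm(a, 0, sqrt(s2_fam))[fam] +
      rnorm(a * b, 0, sqrt(s2_mat))[(fam - 1L) * b + mat] +
      rnorm(a * b * n, 0, sqrt(s2_res)))
}

# Independent chi-square upper tail for df = 1 by numerical integration of
# the explicit density exp(-t/2) / sqrt(2 pi t).
chisq1_tail_numeric <- function(x) {
  stats::integrate(function(t) exp(-t / 2) / sqrt(2 * pi * t),
                   lower = x, upper = Inf, rel.tol = 1e-10)$value
}
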