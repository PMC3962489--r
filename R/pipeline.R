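#' Reproduce the marker-screen report from the bundled panel
#'
#' Runs [marker_screen()] on the bundled marker panel under the
#' random-chromosome null model with 95% exact binomial intervals — the
#' full per-marker and pooled report: detection-failure probabilities,
#' apparent heterozygosity with and without the outlier individual, exact
#' CIs, preferential pairing factors, the Williams-corrected pooled G-test
#' and the heterogeneity G-test.
#'
#' @param output_dir Optional directory; when given, writes
#'   `marker_screen.tsv` (and `marker_screen_excl.tsv` for the
#'   outlier-excluded companion) there.
#' @param ... Passed on to [marker_screen()].
#' @return The `"marker_screen"` object, invisibly when writing files.
#' @examples
#' fit <- reproduce_marker_screen()
#' fit$pooled
#' @export
reproduce_marker_screen <- function(output_dir = NULL, ...) {
  fit <- marker_screen(polyseg_panel(), ...)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_screen_tsv(fit, file.path(output_dir, "marker_screen.tsv"))
    fit_excl <- marker_screen(polyseg_panel(), exclude_outlier = TRUE, ...)
    write_screen_tsv(fit_excl, file.path(output_dir, "marker_screen_excl.tsv"))
    return(invisible(fit))
  }
  fit
}

#' Parameter-recovery simulation study
#'
#' End-to-end check of the inference chain: simulates backcross gamete
#' panels at known preferential pairing factors, re-estimates the factor
#' from the collapsed heterozygous/loss counts, and summarises the
#' recovery across replicates.
#'
#' @param p_true Vector of true preferential pairing factors.
#' @param n_progeny Backcross progeny per replicate panel.
#' @param n_reps Replicates per true value.
#' @param alpha Double reduction rate used in simulation.
#' @param assumption Estimator assumption (see
#'   [estimate_preferential_pairing()]).
#' @param seed Integer seed.
#' @return Data frame with one row per true value: `p_true`, `mean_p_hat`,
#'   `sd_p_hat`, `bias`, `n_reps`, `n_progeny`, plus attribute
#'   `"estimates"` holding the full replicate-by-value matrix.
#' @examples
#' run_simulation_study(p_true = 0.54, n_progeny = 500, n_reps = 20, seed = 1)
#' @export
run_simulation_study <- function(p_true = c(0.46, 0.54, 0.60),
                                 n_progeny = 5000L, n_reps = 200L,
                                 alpha = 0, assumption = "bivalent",
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  est <- sapply(p_true, function(pt) {
    loss_prob <- (1 - wu_gn_frequency(pt, alpha)) / 2
    replicate(n_reps, {
      off <- simulate_cross(founder_duplex(), founder_tester(), pt, alpha,
                            n_progeny)
      calls <- collapse_to_marker_calls(off)
      estimate_preferential_pairing(calls$n_scored, calls$n_loss_G,
                                    assumption)$p_hat
    })
  })
  est <- matrix(est, nrow = n_reps)
  out <- data.frame(p_true = p_true,
                    mean_p_hat = colMeans(est),
                    sd_p_hat = apply(est, 2L, stats::sd),
                    bias = colMeans(est) - p_true,
                    n_reps = n_reps, n_progeny = n_progeny)
  attr(out, "estimates") <- est
  out
}
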