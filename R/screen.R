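#' Screen a marker panel for non-homologous segregation
#'
#' The central analysis of the package: given per-marker heterozygous/loss
#' counts from selfed and backcross progeny classes, computes for each
#' marker and for each pooled class the detection-power probability
#' (failure to observe a quadruple homozygote under the chosen pairing
#' model), apparent heterozygosity (with and without a designated outlier
#' individual), exact binomial confidence intervals, the preferential
#' pairing factor for backcross markers, a Williams-corrected pooled
#' goodness-of-fit G-test against the pairing model, and a heterogeneity
#' G-test across the markers showing band loss.
#'
#' @param panel A `"marker_panel"` data frame (see [read_marker_panel()]),
#'   or a path to a panel TSV. Defaults to the bundled panel.
#' @param model Null pairing model for detection power and the G-test;
#'   default `"random-chromosome"`, the least stringent non-homologous
#'   model.
#' @param conf Confidence level for the exact binomial intervals.
#' @param exclude_outlier Use `n_loss_excl` in place of `n_loss`
#'   throughout (the designated outlier individual's losses removed).
#' @param assumption Pairing assumption for the preferential-pairing
#'   estimator: `"bivalent"` or `"quadrivalent"`.
#' @param design_map Named character vector mapping class labels to
#'   progeny designs (`"self"` or `"backcross"`). Classes not named are
#'   inferred from the label: labels starting `BC` are backcrosses,
#'   anything else is selfed.
#' @return An object of class `"marker_screen"`: a list with data frames
#'   `markers` (per-marker statistics) and `pooled` (per-class pooled
#'   statistics), a list `heterogeneity` of per-class heterogeneity
#'   G-tests, and the settings used. `coef()` extracts the per-marker
#'   preferential pairing factors; `print()` gives a compact report and
#'   `summary()` a long one.
#' @examples
#' fit <- marker_screen()
#' fit
#' coef(fit)
#' @export
marker_screen <- function(panel = polyseg_panel(),
                          model = "random-chromosome",
                          conf = 0.95,
                          exclude_outlier = FALSE,
                          assumption = c("bivalent", "quadrivalent"),
                          design_map = NULL) {
  assumption <- match.arg(assumption)
  if (is.character(panel) && length(panel) == 1L)
    panel <- read_marker_panel(panel)
  panel <- as_marker_panel(as.data.frame(panel))
  model <- match_pairing_model(model)
  if (!is.finite(conf) || conf <= 0 || conf >= 1)
    stop("conf must lie in (0, 1)", call. = FALSE)

  loss <- if (exclude_outlier) panel$n_loss_excl else panel$n_loss
  het <- if (exclude_outlier) panel$n_scored - panel$n_loss_excl else panel$n_het
  design <- vapply(panel$class, function(cl) {
    if (!is.null(design_map) && cl %in% names(design_map)) design_map[[cl]]
    else if (grepl("^BC", cl)) "backcross" else "self"
  }, character(1L))

  per_ci <- lapply(seq_len(nrow(panel)),
                   function(i) clopper_pearson_ci(het[i], panel$n_scored[i], conf))
  p_hat <- vapply(seq_len(nrow(panel)), function(i) {
    if (design[i] != "backcross") return(NA_real_)
    estimate_preferential_pairing(panel$n_scored[i], loss[i], assumption)$p_hat
  }, numeric(1L))

  markers <- data.frame(
    marker_id = panel$marker_id, arm_label = panel$arm_label,
    class = panel$class, design = design,
    n_scored = panel$n_scored, n_het = het, n_loss = loss,
    p_fail = vapply(seq_len(nrow(panel)), function(i)
      prob_fail_to_detect(model, design[i], panel$n_scored[i]), numeric(1L)),
    apparent_het = het / panel$n_scored,
    ci_lower = vapply(per_ci, `[[`, numeric(1L), "lower"),
    ci_upper = vapply(per_ci, `[[`, numeric(1L), "upper"),
    p_hat = p_hat,
    stringsAsFactors = FALSE)

  classes <- unique(panel$class)
  pooled_rows <- list()
  heterogeneity <- list()
  gtests <- list()
  for (cl in classes) {
    idx <- which(panel$class == cl)
    dsn <- design[idx[1L]]
    n <- sum(panel$n_scored[idx]); h <- sum(het[idx]); l <- sum(loss[idx])
    ci <- clopper_pearson_ci(h, n, conf)
    # pooled G-test of (het, loss) against the model's expectation
    g <- gamete_ratios(model)
    geno <- if (dsn == "self") progeny_genotype_frequencies(g)
            else progeny_genotype_frequencies(g, c(0, 0, 1))
    q <- if (dsn == "self") geno[[1L]] + geno[[5L]] else geno[[5L]]
    gt <- gtest_goodness_of_fit(c(h, l), c(1 - q, q), williams = TRUE)
    gtests[[cl]] <- gt
    with_loss <- idx[loss[idx] > 0]
    heterogeneity[[cl]] <- if (length(with_loss) >= 2L)
      heterogeneity_gtest(cbind(het = het[with_loss], loss = loss[with_loss]))
    pooled_rows[[cl]] <- data.frame(
      class = cl, design = dsn, n_markers = length(idx),
      n_scored = n, n_het = h, n_loss = l,
      p_fail = prob_fail_to_detect(model, dsn, n),
      apparent_het = h / n, ci_lower = ci$lower, ci_upper = ci$upper,
      G_adj = gt$G_adj, G_p_value = gt$p_value,
      stringsAsFactors = FALSE)
  }

  structure(list(markers = markers,
                 pooled = do.call(rbind, c(pooled_rows, make.row.names = FALSE)),
                 gtests = gtests, heterogeneity = heterogeneity,
                 model = model, conf = conf, assumption = assumption,
                 exclude_outlier = exclude_outlier, call = match.call()),
            class = "marker_screen")
}

#' @export
print.marker_screen <- function(x, digits = 3L, ...) {
  cat("Marker screen for non-homologous segregation\n")
  cat("  null model: ", x$model, "; ", 100 * x$conf,
      "% exact binomial CIs; estimator assumption: ", x$assumption,
      if (x$exclude_outlier) "; outlier excluded" else "", "\n\n", sep = "")
  m <- x$markers
  out <- data.frame(
    marker = m$marker_id, class = m$class,
    het = sprintf("%d/%d", m$n_het, m$n_scored),
    loss = m$n_loss,
    app_het = round(m$apparent_het, digits),
    ci = sprintf("%.3f-%.3f", m$ci_lower, m$ci_upper),
    p_fail = signif(m$p_fail, 3L),
    p_hat = ifelse(is.na(m$p_hat), "", sprintf("%.2f", m$p_hat)))
  print(out, row.names = FALSE)
  cat("\nPooled classes:\n")
  p <- x$pooled
  out2 <- data.frame(
    class = p$class, markers = p$n_markers,
    het = sprintf("%d/%d", p$n_het, p$n_scored),
    app_het = round(p$apparent_het, digits),
    ci = sprintf("%.3f-%.3f", p$ci_lower, p$ci_upper),
    p_fail = signif(p$p_fail, 3L),
    G_p = signif(p$G_p_value, 3L))
  print(out2, row.names = FALSE)
  for (cl in names(x$heterogeneity)) {
    h <- x$heterogeneity[[cl]]
    if (!is.null(h))
      cat(sprintf("\nHeterogeneity G (%s, markers with loss): G_H = %.2f, df = %d, p = %.2f\n",
                  cl, h$G_adj, h$df, h$p_value))
  }
  invisible(x)
}

#' @export
summary.marker_screen <- function(object, ...) {
  print(object, ...)
  cat("\nPer-class pooled G-tests (Williams-corrected, vs ", object$model,
      "):\n", sep = "")
  for (cl in names(object$gtests)) {
    cat(" ", cl, ": "); print(object$gtests[[cl]])
  }
  invisible(object)
}

#' @export
coef.marker_screen <- function(object, ...) {
  m <- object$markers[!is.na(object$markers$p_hat), ]
  stats::setNames(m$p_hat, m$marker_id)
}

#' Write a marker-screen report as TSV
#'
#' @param x A `"marker_screen"` object.
#' @param path Output file path; per-marker rows followed by pooled rows.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(x, path) {
  stopifnot(inherits(x, "marker_screen"))
  utils::write.table(x$markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat("\n", file = path, append = TRUE)
  suppressWarnings(utils::write.table(x$pooled, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}
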