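#' Read a marker panel file
#'
#' Reads a tab-separated marker panel with columns `marker_id`,
#' `arm_label`, `class`, `n_scored`, `n_het`, `n_loss` and optionally
#' `n_loss_excl` (loss counts after excluding a designated outlier
#' individual; defaults to `n_loss`). Each row is one marker scored in one
#' progeny class; pooled class-level rows are permitted.
#'
#' @param path Path to a TSV file.
#' @return A data frame of class `"marker_panel"`.
#' @seealso [polyseg_panel()] for the bundled backcross/selfed panel.
#' @export
read_marker_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("marker_id", "arm_label", "class", "n_scored", "n_het", "n_loss")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("marker panel ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"n_loss_excl" %in% names(df)) df$n_loss_excl <- df$n_loss
  as_marker_panel(df)
}

#' @rdname read_marker_panel
#' @param df A data frame with the panel columns, validated row by row.
#' @export
as_marker_panel <- function(df) {
  for (col in c("n_scored", "n_het", "n_loss", "n_loss_excl")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] %% 1 != 0)
    if (length(bad))
      stop("marker panel row ", bad[1L], " (", df$marker_id[bad[1L]],
           "): column ", col, " must be a nonnegative integer", call. = FALSE)
  }
  bad <- which(df$n_het + df$n_loss > df$n_scored)
  if (length(bad))
    stop("marker panel row ", bad[1L], " (", df$marker_id[bad[1L]],
         "): n_het + n_loss exceeds n_scored", call. = FALSE)
  bad <- which(df$n_loss_excl > df$n_loss)
  if (length(bad))
    stop("marker panel row ", bad[1L], " (", df$marker_id[bad[1L]],
         "): n_loss_excl exceeds n_loss", call. = FALSE)
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' Bundled marker panel from the original screen
#'
#' The marker counts of the original synthetic-allotetraploid screen: two
#' pooled selfed-lineage classes (S2G and S2N, 13 microsatellite markers
#' each, no band loss) and seven per-marker backcross (BC1N) rows of 48
#' scored individuals each, with 10 band-loss calls in total, of which 6
#' trace to a single outlier individual (`n_loss_excl` removes them).
#'
#' @return A `"marker_panel"` data frame (see [read_marker_panel()]).
#' @examples
#' panel <- polyseg_panel()
#' subset(panel, class == "BC1N")
#' @export
polyseg_panel <- function() {
  read_marker_panel(system.file("extdata", "neoallotetraploid_panel.tsv",
                                package = "polyseg", mustWork = TRUE))
}
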