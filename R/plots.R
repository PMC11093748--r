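#' ES scatter with confidence zones
#'
#' One panel per TCR: epitopes along the x axis (library order), mean ES on
#' the y axis, dashed lines at the high (green) and low (orange)
#' confidence thresholds — the standard way screen results are inspected.
#'
#' @param object `sabr_tcr_scores` tibble (optionally after
#'   [call_hits()] with `keep_all = TRUE`).
#' @param zones optional `sabr_zones` to draw thresholds.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sabr_tcr_scores <- function(object, zones = attr(object, "zones"), ...) {
  df <- tibble::as_tibble(object)
  df$rank <- stats::ave(seq_len(nrow(df)), df$tcr, FUN = seq_along)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mean_es)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~tcr) +
    ggplot2::labs(x = "epitope", y = "mean enrichment score (CPM)") +
    ggplot2::theme_bw()
  if (!is.null(zones)) {
    p <- p +
      ggplot2::geom_hline(yintercept = zones$high_threshold,
                          linetype = "dashed", colour = "darkgreen") +
      ggplot2::geom_hline(yintercept = zones$low_threshold,
                          linetype = "dashed", colour = "orange")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Library representation histogram
#'
#' Distribution of per-epitope abundance (or read counts) on a log10 axis,
#' used to judge library evenness after cloning or simulation.
#'
#' @param library tibble with an `abundance` column, or a `sabr_counts`
#'   tibble plus a `sample` name.
#' @param sample sample column to plot when given counts.
#' @return a ggplot object.
#' @export
plot_library_representation <- function(library, sample = NULL) {
  x <- if (!is.null(sample)) library[[sample]] else library$abundance
  ggplot2::ggplot(tibble::tibble(x = x[x > 0]), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = if (is.null(sample)) "epitope abundance" else "reads",
                  y = "epitopes") +
    ggplot2::theme_bw()
}
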