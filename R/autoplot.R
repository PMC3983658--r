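# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an oscillation profile
#'
#' Correlation per timepoint with the per-timepoint significance band; the
#' phase label of each timepoint is shown on the x axis.
#'
#' @param object An [oscillation_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.oscillation_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = -.data$critical_r, ymax = .data$critical_r),
      fill = "grey85", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase)) +
    ggplot2::labs(
      x = "time since release (min)",
      y = "Pearson r (expression vs T_rep)",
      colour = "phase",
      title = sprintf("Oscillation profile (%s genes)",
                      attr(object, "gene_filter") %||% "all"),
      subtitle = sprintf("band: |r| below the two-tailed alpha = %g threshold",
                         attr(object, "alpha"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a T_rep moving average along the peak-expression ordering
#'
#' @param object A [trep_moving_average()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trep_moving_average <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_index, y = .data$mean_trep)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_trep - .data$se_trep,
                                      ymax = .data$mean_trep + .data$se_trep),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window (genes ordered by peak expression time)",
                  y = "mean T_rep (min)",
                  title = "T_rep moving average along the cell cycle") +
    ggplot2::theme_minimal()
}

#' Plot median expression by T_rep decile
#'
#' @param object A [decile_median_expression()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trep_decile_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$decile),
                                   y = .data$median_expression)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "T_rep decile (1 = earliest)", y = "median expression",
                  title = "Expression by replication-timing decile") +
    ggplot2::theme_minimal()
}

#' Plot a replication-timing profile with optional peaks
#'
#' @param object A [trep_profile()].
#' @param peaks Optional peak table from [call_early_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trep_profile <- function(object, peaks = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position / 1e3, y = .data$trep)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (kb)", y = "T_rep (min; early at top)",
                  title = "Replication-timing profile") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$peak_position / 1e3, y = .data$peak_trep),
      colour = "firebrick")
  }
  p
}
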