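#' Probability-density curves of log2(K8/K14) per condition
#'
#' Gaussian kernel density with Scott's bandwidth, one curve per condition;
#' the underlying histogram is available from the records themselves, so no
#' scientific claim rests on the smoother.
#'
#' @param records Log-ratio record tibble.
#' @param scheme Optional [fit_bin_scheme()] result; when given, the three
#'   bin boundaries are drawn as dashed verticals.
#' @return A ggplot object.
#' @export
plot_ratio_density <- function(records, scheme = NULL) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$log2_ratio,
                                    colour = .data$condition)) +
    ggplot2::geom_density(bw = "nrd") +
    ggplot2::labs(x = expression(log[2](K8 / K14)), y = "density",
                  colour = "condition") +
    ggplot2::theme_minimal()
  if (!is.null(scheme))
    p <- p + ggplot2::geom_vline(
      xintercept = c(scheme$q25, scheme$q50, scheme$q75), linetype = "dashed",
      colour = "grey40")
  p
}

#' Violin plot of log2(K8/K14) per condition or patient
#'
#' @param records Log-ratio record tibble.
#' @param by Grouping column: `"condition"` (default) or `"patient_id"`.
#' @return A ggplot object.
#' @export
plot_ratio_violin <- function(records, by = "condition") {
  ggplot2::ggplot(records, ggplot2::aes(x = .data[[by]],
                                        y = .data$log2_ratio,
                                        fill = .data[[by]])) +
    ggplot2::geom_violin(scale = "width", trim = FALSE) +
    ggplot2::labs(x = NULL, y = expression(log[2](K8 / K14))) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bin-occupancy heatmap
#'
#' Rows are conditions, columns are bins 1-4, cell values are the percentage
#' of sections in the bin.
#'
#' @param dists Named list of `bin_distribution` objects.
#' @return A ggplot object.
#' @export
plot_bin_heatmap <- function(dists) {
  tab <- distribution_table(dists)
  tab$percent <- 100 * tab$prob
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$bin),
                                    y = .data$condition,
                                    fill = .data$percent)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "bin", y = NULL, fill = "% sections") +
    ggplot2::theme_minimal()
}

#' Marker-redundancy scatter plot
#'
#' @param x,y Paired per-section measurements.
#' @param marker_x,marker_y Axis labels.
#' @return A ggplot object with the fitted least-squares line.
#' @export
plot_marker_scatter <- function(x, y, marker_x = "x", marker_y = "y") {
  df <- tibble::tibble(x = x, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = marker_x, y = marker_y) +
    ggplot2::theme_minimal()
}
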