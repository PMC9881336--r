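#' Spaghetti plot of one metric across speeds
#'
#' One line per participant across their speeds, coloured by group — the
#' standard display for speed-dependent change in a gait metric.
#'
#' @param metrics Tibble with `participant_id`, `group`, `speed` and the
#'   metric column.
#' @param metric Metric column name.
#' @return A ggplot object.
#' @export
plot_metric_speed <- function(metrics, metric = "sla") {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$speed, y = .data[[metric]],
                               group = .data$participant_id,
                               colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.45) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(stroke = "#c0392b",
                                            neurotypical = "#2c3e50")) +
    ggplot2::labs(x = "gait speed (m/s)", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}

#' PCA view of a clustering result
#'
#' Participants in the plane of the first two principal components of the
#' scaled metrics, coloured by cluster. The projection is for display
#' only; clustering runs in the full seven-dimensional scaled space.
#'
#' @param object A `gait_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gait_clusters
#' @export
autoplot.gait_clusters <- function(object, ...) {
  d <- tidy(object)
  ev <- object$pca_explained
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                  colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ev[2]),
      colour = "cluster",
      title = if (!is.na(object$condition)) object$condition else NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Variable-importance bar chart
#'
#' @param object A `gait_clusters` object.
#' @return A ggplot object showing the permutation importance (mean
#'   decrease in out-of-bag accuracy) of each metric.
#' @export
plot_importance <- function(object) {
  d <- object$importance
  d$metric <- factor(d$metric, levels = rev(d$metric))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$metric)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::labs(x = "mean decrease in accuracy", y = NULL) +
    ggplot2::theme_minimal()
}
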