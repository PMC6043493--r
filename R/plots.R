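# Plotting: class distributions of ROI means and cross-metric scatterplots.

#' Plot the distribution of ROI means per tissue class and metric
#'
#' @param object a `roi_table`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.roi_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tissue_class, y = .data$mean_value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric_name, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ROI mean value") +
    ggplot2::theme_minimal()
}

#' Cross-metric scatterplot of ROI means
#'
#' One point per subject-by-ROI mean, coloured by tissue class; the visual
#' counterpart of the pooled correlation table.
#'
#' @param table a `roi_table` containing both metrics (calibrated table from
#'   [compare_metrics()] or raw).
#' @param metric_x,metric_y metric names.
#' @return A ggplot object.
#' @export
plot_metric_scatter <- function(table, metric_x, metric_y) {
  wide <- .wide_metrics(table, c(metric_x, metric_y))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[metric_x]],
                                     y = .data[[metric_y]],
                                     colour = .data$tissue_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey30") +
    ggplot2::labs(x = metric_x, y = metric_y, colour = "tissue class") +
    ggplot2::theme_minimal()
}

#' Plot the pooled correlation matrix of a comparison report
#'
#' @param object a `comparison_report`.
#' @param ... unused.
#' @return A ggplot object showing rho with its confidence interval per
#'   region and metric pair.
#' @export
autoplot.comparison_report <- function(object, ...) {
  dat <- dplyr::mutate(object$table2,
                       pair = paste(.data$metric_a, .data$metric_b, sep = "\nvs "))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pair, y = .data$rho)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~region, nrow = 1) +
    ggplot2::labs(x = NULL, y = "Spearman rho (95% CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}
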