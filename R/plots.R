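#' Plot a smoothed viewpoint interaction profile
#'
#' Line plot of the smoothed normalized-count profile of one viewpoint, one
#' line per condition — the line-plot view of a Capture-C viewpoint.
#'
#' @param profile Output of [viewpoint_profile()].
#' @return A ggplot object.
#' @export
plot_viewpoint_profile <- function(profile) {
  mid <- (profile$start + profile$end) / 2
  ggplot2::ggplot(
    profile |> mutate(.mid = mid),
    ggplot2::aes(x = .data$.mid, y = .data$smoothed,
                 colour = .data$condition_id)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)", y = "normalized count (smoothed)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Boxplot of per-peak interaction metrics by condition
#'
#' The comparative boxplot view of merged interaction peaks: one box per
#' condition of the span-averaged interaction score (or normalized count).
#'
#' @param peak_values Output of [aggregate_peaks()].
#' @param metric `"mean_score"` (default) or `"mean_norm_count"`.
#' @return A ggplot object.
#' @export
plot_condition_scores <- function(peak_values, metric = "mean_score") {
  ggplot2::ggplot(
    peak_values,
    ggplot2::aes(x = .data$condition_id, y = .data[[metric]])
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "condition", y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a resampling null distribution
#'
#' Histogram of the matched-resampling null with the observed statistic marked;
#' the empirical p-value is shown in the subtitle.
#'
#' @param object A `promcap_resample` object from [empirical_p()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.promcap_resample <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null_values),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "#2166ac", linewidth = 1) +
    ggplot2::labs(
      x = "statistic (matched null)", y = "samplings",
      subtitle = sprintf("observed = %.4g, empirical p (%s) = %.4g",
                         object$observed, object$alternative, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
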