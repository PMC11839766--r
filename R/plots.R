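#' Plot a STAGES cross-tabulation as a heatmap
#'
#' @param object A `stages_crosstab`.
#' @param ... Unused.
#' @return A ggplot object: counts as tiles over the 12 x 12 grid, rater A
#'   on the vertical axis.
#' @method autoplot stages_crosstab
#' @export
autoplot.stages_crosstab <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)), stringsAsFactors = FALSE)
  names(df) <- c("rater_a", "rater_b", "count")
  labels <- format_level(stages_grid())
  df$rater_a <- factor(df$rater_a, levels = rev(labels))
  df$rater_b <- factor(df$rater_b, levels = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rater_b, y = .data$rater_a,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$count > 0, .data$count, "")),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Rater B (protocol)", y = "Rater A (expert)",
                  fill = "Count",
                  title = sprintf("Paired STAGES scores (n = %d)",
                                  attr(object, "n"))) +
    ggplot2::theme_minimal()
}

#' Plot subsample mean-stability against sample size
#'
#' @param data Output of [subsample_stability()].
#' @return A ggplot object: mean absolute difference from the full-set mean,
#'   with a +/- 1 sd ribbon, against subsample size.
#' @export
plot_subsample_stability <- function(data) {
  stopifnot(all(c("sample_size", "mean_abs_diff", "sd_abs_diff") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$sample_size,
                                     y = .data$mean_abs_diff)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$mean_abs_diff - .data$sd_abs_diff, 0),
                   ymax = .data$mean_abs_diff + .data$sd_abs_diff),
      fill = "steelblue", alpha = 0.2
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "Items per subsample",
                  y = "Mean |subsample mean - full-set mean|",
                  title = "Stability of the mean score by item count") +
    ggplot2::theme_minimal()
}

#' Plot run-count regression slopes by window start
#'
#' @param rows Output of [run_count_regression()].
#' @return A ggplot object: the fitted slope for each window start, per
#'   quantity; flat slopes indicate the median outcome has stabilised.
#' @export
plot_run_regression <- function(rows) {
  stopifnot(all(c("window_start", "quantity", "slope") %in% names(rows)))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$window_start, y = .data$slope,
                                     colour = .data$quantity)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Window start (runs)", y = "OLS slope of median on runs",
                  colour = "Quantity",
                  title = "Run-count stabilisation regression") +
    ggplot2::theme_minimal()
}
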