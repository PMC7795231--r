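# ggplot2 displays for the main result objects.

#' Plot a posture confusion matrix
#'
#' Heatmap with counts, truth on the x axis and predictions on the y axis.
#'
#' @param object A `posture_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot posture_confusion
#' @export
autoplot.posture_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "True posture", y = "Predicted posture", fill = "Windows") +
    ggplot2::theme_minimal()
}

#' Plot an accuracy distribution
#'
#' Box-style summary of the per-trial held-out accuracies: the box spans the
#' 25th to 75th percentile, the bold line marks the mean, dots mark Tukey
#' outliers.
#'
#' @param object An `accuracy_distribution` from [repeated_trials()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_distribution
#' @export
autoplot.accuracy_distribution <- function(object, ...) {
  s <- object$summary
  df <- tidy(object)
  box <- tibble(
    x = toupper(object$algorithm), q25 = s$q25, q75 = s$q75, mean = s$mean
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = box,
      ggplot2::aes(xmin = 0.7, xmax = 1.3, ymin = .data$q25, ymax = .data$q75),
      fill = "grey85", colour = "grey30"
    ) +
    ggplot2::geom_segment(
      data = box,
      ggplot2::aes(x = 0.7, xend = 1.3, y = .data$mean, yend = .data$mean),
      linewidth = 1.2
    ) +
    ggplot2::geom_point(
      data = df[df$outlier, ],
      ggplot2::aes(x = 1, y = .data$accuracy), shape = 1
    ) +
    ggplot2::scale_x_continuous(breaks = 1, labels = box$x, limits = c(0.4, 1.6)) +
    ggplot2::labs(
      x = NULL, y = "Held-out accuracy",
      title = sprintf("%d repeated trials", object$n_trials)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sensor stream
#'
#' Per-axis acceleration traces over time.
#'
#' @param object A `sensor_stream`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensor_stream
#' @export
autoplot.sensor_stream <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("ax", "ay", "az"), names_to = "axis", values_to = "g")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp_ms / 1000, y = .data$g,
                                   colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time (s)", y = "Acceleration (G)",
      title = sprintf("%s sensor stream", stream_site(object))
    ) +
    ggplot2::theme_minimal()
}
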