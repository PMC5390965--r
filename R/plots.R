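#' Plot a developmental trajectory
#'
#' Fitted curve with the 95% bootstrap confidence region, optionally over
#' the raw participant points.
#'
#' @param fit a [fit_trajectory()] object.
#' @param data optional wide per-participant data frame for the raw
#'   points.
#' @return a ggplot object.
#' @export
plot_trajectory <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "trajectory_fit"))
  d <- data.frame(age = fit$age, fitted = fit$fitted,
                  lo = fit$ci_lower, hi = fit$ci_upper)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age))
  if (!is.null(data) && fit$variable %in% names(data))
    p <- p + ggplot2::geom_point(
      data = data.frame(age = data$age, y = data[[fit$variable]]),
      ggplot2::aes(x = .data$age, y = .data$y),
      alpha = 0.15, size = 0.4, colour = "grey40")
  if (!all(is.na(d$lo)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.3)
  p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                         colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "Age (years)", y = fit$variable) +
    ggplot2::theme_minimal()
}

#' Plot the speed-accuracy developmental path
#'
#' The parametric (CT, complexity) curve traced by age, annotated at
#' decade marks.
#'
#' @param path a [speed_accuracy_path()].
#' @return a ggplot object.
#' @export
plot_speed_accuracy <- function(path) {
  stopifnot(inherits(path, "speed_accuracy_path"))
  marks <- path[path$age %in% seq(10, 90, 10), ]
  ggplot2::ggplot(path, ggplot2::aes(x = .data$ct, y = .data$z)) +
    ggplot2::geom_path(colour = "steelblue", linewidth = 1) +
    ggplot2::geom_point(data = marks, size = 1.5) +
    ggplot2::geom_text(data = marks, ggplot2::aes(label = .data$age),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Completion time (s)", y = "Normalized complexity") +
    ggplot2::theme_minimal()
}
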