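#' Plot class trajectories of a mixture model
#'
#' Draws the three distributional parameters (attempt probability, mean
#' hours, day-to-day SD) over the follow-up window, one curve per class.
#'
#' @param object a [hurdle_mixture()] or `hurdletraj_fit`.
#' @param days day range to draw (default 1..90).
#' @param ... unused.
#' @return a ggplot object faceted by parameter.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.hurdle_mixture <- function(object, days = 1:90, ...) {
  tab <- trajectory_table(object, days = days)
  long <- tidyr::pivot_longer(
    tab, c("attempt_prob", "mean_hours", "sd_hours"),
    names_to = "parameter", values_to = "value"
  )
  long$parameter <- factor(long$parameter,
                           levels = c("attempt_prob", "mean_hours", "sd_hours"),
                           labels = c("attempt probability 1 - nu",
                                      "mean time mu (h)", "SD time sigma (h)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value,
                                     colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "day of therapy", y = NULL, colour = "class") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hurdle_mixture
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.hurdletraj_fit <- function(object, days = 1:90, ...) {
  autoplot.hurdle_mixture(object$model, days = days, ...)
}

#' Worm plot of randomized quantile residuals
#'
#' @param worm output of [residual_diagnostics()].
#' @param envelope optional output of [worm_envelope()] drawn as a ribbon.
#' @return a ggplot object.
#' @export
plot_worm <- function(worm, envelope = NULL) {
  p <- ggplot2::ggplot(worm, ggplot2::aes(x = .data$theoretical_quantile,
                                          y = .data$detrended_deviation)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "theoretical normal quantile",
                  y = "deviation from normality") +
    ggplot2::theme_minimal()
  if (!is.null(envelope)) {
    p <- p + ggplot2::geom_ribbon(
      data = envelope$pointwise,
      ggplot2::aes(x = .data$theoretical_quantile, ymin = .data$lower,
                   ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.2
    )
  }
  p
}
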