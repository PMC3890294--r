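#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_abline scale_x_log10 scale_y_log10 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a log-binned distribution on log-log axes
#'
#' @param object A `binned_dist` from [log_bin()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.binned_dist <- function(object, ...) {
  pts <- dplyr::filter(as_tibble(object), .data$count > 0)
  ggplot(pts, aes(x = .data$center, y = .data$density)) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "value", y = "probability density") +
    theme_minimal()
}

#' Plot a DFA fluctuation function
#'
#' @param object A `dfa_result` from [dfa()].
#' @param ... Unused.
#' @return A ggplot of F(l) against box size on log-log axes.
#' @exportS3Method ggplot2::autoplot
autoplot.dfa_result <- function(object, ...) {
  ggplot(object$fluctuation, aes(x = .data$box_size, y = .data$F)) +
    geom_point() + geom_line(alpha = 0.4) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "box size l", y = "fluctuation F(l)",
         title = sprintf("DFA: H = %.3f", object$hurst)) +
    theme_minimal()
}

#' Plot a correlation lag-decay profile
#'
#' @param object A `lag_decay` tibble from [tau_lag_profile()].
#' @param ... Unused.
#' @return A ggplot of tau against lag on log-log axes, with the null CI.
#' @exportS3Method ggplot2::autoplot
autoplot.lag_decay <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$lag, y = .data$tau)) +
    geom_line(aes(y = .data$ci_halfwidth), linetype = "dashed") +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "lag", y = "Kendall's tau") +
    theme_minimal()
}

#' Plot a consecutive-displacement scatter pattern
#'
#' @param object A `scatter_pattern` from [scatter_correlation_pattern()].
#' @param ... Unused.
#' @return A ggplot heat map of the consecutive-pair density with the
#'   diagonal marked.
#' @exportS3Method ggplot2::autoplot
autoplot.scatter_pattern <- function(object, ...) {
  ggplot(object$grid,
         aes(x = .data$x_center, y = .data$y_center, fill = .data$count)) +
    geom_tile() +
    geom_abline(slope = 1, intercept = 0, colour = "white",
                linetype = "dashed") +
    scale_x_log10() + scale_y_log10() +
    labs(x = expression(Delta * r[n]), y = expression(Delta * r[n + 1]),
         fill = "pairs") +
    theme_minimal()
}

#' Plot the speed-displacement pattern
#'
#' @param object A `speed_pattern` from [speed_displacement_pattern()].
#' @param ... Unused.
#' @return A ggplot of the per-movement point cloud with the binned
#'   median-speed curve.
#' @exportS3Method ggplot2::autoplot
autoplot.speed_pattern <- function(object, ...) {
  ggplot(object$points, aes(x = .data$displacement, y = .data$speed)) +
    geom_point(alpha = 0.15, size = 0.6) +
    geom_line(data = object$curve,
              aes(x = .data$center, y = .data$median_speed),
              colour = "red") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "displacement (m)", y = "speed (m/s)") +
    theme_minimal()
}
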