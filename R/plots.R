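# --- ggplot2 displays --------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an angular histogram
#'
#' Bar display of the 16-bin normalised direction frequencies, with a
#' dashed line at the uniform level 1/16.
#'
#' @param object An `angular_histogram`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot angular_histogram
#' @export
autoplot.angular_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$freq)) +
    ggplot2::geom_col(width = 20, fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1 / nrow(object), linetype = "dashed",
                        colour = "grey55") +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 45)) +
    ggplot2::labs(x = "direction (deg)", y = "proportion of trials") +
    ggplot2::theme_minimal()
}

#' Plot a per-bin histogram-difference permutation test
#'
#' Observed per-bin frequency differences (test minus baseline session)
#' with significant bins highlighted.
#'
#' @param object A `hist_perm_test`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot hist_perm_test
#' @export
autoplot.hist_perm_test <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin_center,
                                    y = .data$observed_diff,
                                    fill = .data$significant)) +
    ggplot2::geom_col(width = 20) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               name = paste0("p < ", object$alpha)) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 45)) +
    ggplot2::labs(x = "direction (deg)",
                  y = sprintf("frequency difference (%s - %s)",
                              object$comparison, object$baseline)) +
    ggplot2::theme_minimal()
}

#' Plot a serial-dependence curve
#'
#' Group-mean signed angular error as a function of the direction change
#' between consecutive trials, with a between-subject SEM ribbon.
#'
#' @param object A `serial_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot serial_curve
#' @export
autoplot.serial_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$bin,
                                             y = .data$mean_delta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_delta - .data$sem,
                                      ymax = .data$mean_delta + .data$sem),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 45)) +
    ggplot2::labs(x = "direction change from previous trial (deg)",
                  y = "mean angular error (deg)") +
    ggplot2::theme_minimal()
}

#' Plot projected eye velocity over time
#'
#' Mean projected velocity trace with the three analysis windows shaded
#' (anticipation, open-loop acceleration, steady state).
#'
#' @param vel Velocity tibble with `t_ms` and either `vproj` or
#'   `vx`/`vy` plus `theta`.
#' @param theta Stimulus direction used when `vproj` is absent.
#' @param windows List of windows to shade.
#' @return A ggplot object.
#' @export
plot_projected_velocity <- function(vel, theta = 0,
                                    windows = list(
                                      anticipation = c(-50, 100),
                                      acceleration = c(100, 220),
                                      steady = c(400, 600))) {
  if (!"vproj" %in% names(vel)) {
    vel$vproj <- project_velocity(vel$vx, vel$vy, theta)
  }
  shade <- tibble::tibble(
    phase = names(windows),
    xmin = vapply(windows, `[`, numeric(1), 1),
    xmax = vapply(windows, `[`, numeric(1), 2)
  )
  ggplot2::ggplot(vel, ggplot2::aes(x = .data$t_ms, y = .data$vproj)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$phase),
                       alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = "projected eye velocity (deg/s)") +
    ggplot2::theme_minimal()
}
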