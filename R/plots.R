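#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Enzyme position together with the filament's shrinking- and
#' growing-end positions over time.
#'
#' @param object A `ratchet_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratchet_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("t", "x", "x_S", "x_G")],
    cols = c("x", "x_S", "x_G"),
    names_to = "series", values_to = "position")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$position,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(x = "grey25", x_S = "#7a0177", x_G = "#c994c7"),
      labels = c(x = "enzyme", x_S = "shrinking end",
                 x_G = "growing end")) +
    ggplot2::labs(x = "time (s)", y = "position (nm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a propensity phase diagram
#'
#' Tiles of end-tracking propensity over the swept parameter plane with
#' the 50% phase boundary emphasised.
#'
#' @param object A `ratchet_phase_diagram`.
#' @param log_axes Log-scale the axes (sensible for diffusion sweeps).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratchet_phase_diagram <- function(object, log_axes = TRUE, ...) {
  axes <- attr(object, "axes")
  thr <- attr(object, "threshold")
  gg <- ggplot2::ggplot(object,
                        ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                     fill = .data$propensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "white", mid = "#9ecae1",
                                  high = "#08519c", midpoint = thr,
                                  limits = c(0, 1)) +
    ggplot2::labs(fill = "propensity") +
    ggplot2::theme_minimal()
  if (log_axes && axes[1] %in% c("D")) {
    gg <- gg + ggplot2::scale_x_log10()
  }
  if (log_axes && axes[2] %in% c("D")) {
    gg <- gg + ggplot2::scale_y_log10()
  }
  gg
}

#' Plot processivity curves
#'
#' Mean persistent-run duration and net run distance against treadmilling
#' speed, with bootstrap confidence ribbons.
#'
#' @param object A `ratchet_processivity` from
#'   [run_length_duration_curves()].
#' @param ... Unused.
#' @return A ggplot (two facets).
#' @export
autoplot.ratchet_processivity <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(v_z = object$v_z, what = "duration (s)",
                   mean = object$mean_duration, lo = object$duration_lo,
                   hi = object$duration_hi),
    tibble::tibble(v_z = object$v_z, what = "run distance (nm)",
                   mean = object$mean_distance, lo = object$distance_lo,
                   hi = object$distance_hi))
  ggplot2::ggplot(df, ggplot2::aes(.data$v_z, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "treadmilling speed (nm/s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a normalized off-rate (activity) curve
#'
#' @param object A `ratchet_activity` from [activity_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratchet_activity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$v_z,
                                       .data$relative_off_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored_dominated)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "treadmilling speed (nm/s)",
                  y = "relative off-rate (activity proxy)") +
    ggplot2::theme_minimal()
}

#' Plot an MSD fit
#'
#' @param object An `msd_fit`.
#' @param ... Unused.
#' @return A ggplot of the empirical MSD and the fitted
#'   `4 D t^alpha + D0` curve.
#' @export
autoplot.msd_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(.data$lag, .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "#2b8cbe") +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (nm^2))) +
    ggplot2::theme_minimal()
}

#' Plot a speed-distribution mixture fit
#'
#' Histogram of the speed samples with the fitted slow/fast log-normal
#' components overlaid.
#'
#' @param object A `lognormal_mixture`.
#' @param speeds The speed samples the fit was computed from.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_mixture <- function(object, speeds, bins = 30, ...) {
  stopifnot(inherits(object, "lognormal_mixture"))
  grid <- seq(min(speeds), max(speeds), length.out = 200)
  comp <- dplyr::bind_rows(
    tibble::tibble(x = grid, component = "slow",
                   density = object$P *
                     stats::dlnorm(grid, object$mu1, object$sigma1)),
    tibble::tibble(x = grid, component = "fast",
                   density = (1 - object$P) *
                     stats::dlnorm(grid, object$mu2, object$sigma2)))
  ggplot2::ggplot(tibble::tibble(speed = speeds),
                  ggplot2::aes(.data$speed)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85",
                            colour = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(.data$x, .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "speed (nm/s)", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
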