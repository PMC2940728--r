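#' Plot methods
#'
#' `autoplot()` methods for the result types: free-energy profiles (`F_H`
#' and `F_C` against the level), anomalous-exponent profiles with +-2 SE
#' ribbons, stride scans of the cut partition function with the two-line
#' ballistic fit, MSD curves with diffusive/sub-diffusive guide slopes, and
#' optimization traces.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot.
#' @name difftrace-autoplot
NULL

#' @rdname difftrace-autoplot
#' @export
autoplot.hist_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !.data$masked),
                  ggplot2::aes(.data$level, .data$F_H)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate", y = "F_H (kT)",
                  title = "Histogram free-energy profile") +
    ggplot2::theme_minimal()
}

#' @rdname difftrace-autoplot
#' @export
autoplot.cut_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !.data$masked),
                  ggplot2::aes(.data$level, .data$F_C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate", y = "F_C (kT)",
                  title = sprintf("Cut free-energy profile (stride %d)",
                                  attr(object, "k"))) +
    ggplot2::theme_minimal()
}

#' @rdname difftrace-autoplot
#' @export
autoplot.diffusion_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !.data$masked),
                  ggplot2::aes(.data$level, .data$D)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate", y = "D(x)",
                  title = "Coordinate-dependent diffusion coefficient") +
    ggplot2::theme_minimal()
}

#' @rdname difftrace-autoplot
#' @export
autoplot.alpha_profile <- function(object, ...) {
  dat <- dplyr::filter(object, !.data$masked)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$level, .data$alpha))
  if (any(is.finite(dat$se)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$alpha - 2 * .data$se,
                   ymax = .data$alpha + 2 * .data$se), alpha = 0.2)
  p + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "reaction coordinate", y = expression(alpha),
                  title = "Anomalous-diffusion exponent profile") +
    ggplot2::theme_minimal()
}

#' @rdname difftrace-autoplot
#' @export
autoplot.cut_scan <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$Z_C > 0),
                  ggplot2::aes(.data$k, .data$Z_C)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sampling interval (frames)", y = "Z_C",
                  title = sprintf("Cut partition function at level %.3g",
                                  attr(object, "level"))) +
    ggplot2::theme_minimal()
}

#' @rdname difftrace-autoplot
#' @export
autoplot.ballistic_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(.data$k, .data$Z_C)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$Z_C_fit), colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sampling interval (frames)", y = "Z_C",
                  title = sprintf("Two-line ballistic fit (%s)",
                                  object$regime)) +
    ggplot2::theme_minimal()
}

#' @rdname difftrace-autoplot
#' @export
autoplot.msd_curve <- function(object, ...) {
  dat <- dplyr::filter(object, is.finite(.data$msd) & .data$msd > 0)
  ref <- 2 * dat$time                  # diffusive MSD with D = 1
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = ref), linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time", y = "MSD",
                  title = sprintf("MSD from window at %.3g (gamma = %.2f)",
                                  attr(object, "level"),
                                  attr(object, "gamma"))) +
    ggplot2::theme_minimal()
}

#' @rdname difftrace-autoplot
#' @export
autoplot.opt_trace <- function(object, ...) {
  ggplot2::ggplot(object$steps, ggplot2::aes(.data$proposal, .data$objective)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::labs(x = "proposal", y = "objective (round-trip mfpt)",
                  title = "Accepted optimization steps") +
    ggplot2::theme_minimal()
}
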