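#' Broom-style tidiers
#'
#' `tidy()` returns per-term / per-step tibbles, `glance()` one-row model
#' summaries, for the fitted objects (`ballistic_fit`, `opt_trace`,
#' `kinetics_result`, `msd_curve`).
#'
#' @param x the fitted object.
#' @param ... unused.
#' @return a tibble.
#' @name difftrace-tidiers
NULL

#' @rdname difftrace-tidiers
#' @export
tidy.ballistic_fit <- function(x, ...) {
  tibble(term = c("alpha", "Z_bal", "t_bal", "w"),
         estimate = c(x$alpha, x$Z_bal, x$t_bal, x$w))
}

#' @rdname difftrace-tidiers
#' @export
glance.ballistic_fit <- function(x, ...) {
  tibble(regime = x$regime, alpha = x$alpha, Z_bal = x$Z_bal,
         t_bal = x$t_bal, w = x$w, rss = x$rss,
         n_strides = nrow(x$fitted))
}

#' @rdname difftrace-tidiers
#' @export
tidy.opt_trace <- function(x, ...) x$steps

#' @rdname difftrace-tidiers
#' @export
glance.opt_trace <- function(x, ...) {
  tibble(family = x$family, n_proposals = x$n_proposals,
         n_accepted = nrow(x$steps), objective_init = x$objective_init,
         objective_final = x$objective_final)
}

#' @rdname difftrace-tidiers
#' @export
glance.kinetics_result <- function(x, ...) {
  tibble(mfpt_forward = x$mfpt_forward, mfpt_backward = x$mfpt_backward,
         n_events_est = x$n_events_est, x_TS = x$x_TS,
         F_C_TS = x$F_C_TS, barrier_height_kT = x$barrier_height_kT,
         duration = x$duration)
}

#' @rdname difftrace-tidiers
#' @export
glance.msd_curve <- function(x, ...) {
  tibble(gamma = attr(x, "gamma"), alpha = attr(x, "alpha"),
         n_origins = attr(x, "n_origins"), level = attr(x, "level"),
         half_width = attr(x, "half_width"))
}
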