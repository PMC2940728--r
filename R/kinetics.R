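#' Kramers mean first passage time on a free-energy profile
#'
#' Integrates the Kramers double integral for overdamped diffusion on the
#' profile, with a reflecting boundary at the data edge on the start side and
#' an absorbing boundary at the target:
#' `mfpt(a -> b) = int_a^b dy  Phi(y) / (D(y) rho(y))`,
#' where `rho` is the normalized equilibrium density and `Phi` the
#' cumulative mass from the reflecting edge (for `a > b` the integral runs
#' from `b` to `a` with `Phi` measured from the right edge).  On the natural
#' coordinate `D = 1`; for a flat profile on `[0, L]` the closed form is
#' `L^2 / (2 D)`.
#'
#' Quadrature is trapezoidal over unmasked bin midpoints; masked interior
#' gaps wider than `max_gap` bins are an error (the profile does not support
#' the integral there).
#'
#' @param hist a [histogram_profile()] (of the natural coordinate, or of a
#'   raw coordinate if `diffusion` is supplied).
#' @param a,b start and target positions on the coordinate.
#' @param diffusion optional [diffusion_profile()] on the same level grid;
#'   `NULL` assumes `D = 1`.
#' @param max_gap widest tolerated run of masked interior bins.
#' @return the mean first passage time (time units of the series).
#' @export
kramers_mfpt <- function(hist, a, b, diffusion = NULL, max_gap = 3) {
  stopifnot(inherits(hist, "hist_profile"))
  edges <- attr(hist, "edges")
  tol <- stats::median(diff(edges)) / 2     # endpoints may sit half a bin out
  if (a < edges[1] - tol || a > edges[length(edges)] + tol ||
      b < edges[1] - tol || b > edges[length(edges)] + tol)
    abort("a and b must lie within the profile's support")
  if (a == b) return(0)
  a <- min(max(a, edges[1]), edges[length(edges)])
  b <- min(max(b, edges[1]), edges[length(edges)])
  ki <- kramers_bins(hist, diffusion, from_left = a < b, max_gap,
                     lo = min(a, b), hi = max(a, b))
  kramers_sum(ki, min(a, b), max(a, b))
}

# Per-bin integrand f_i = Phi_i / (D_i rho_i) with edges; the mfpt is a
# midpoint-rule bin sum, which for equal-population bins is invariant under
# monotone reparametrization of the coordinate (Phi, per-bin mass, and the
# crossing counts behind D all are).
kramers_bins <- function(hist, diffusion, from_left, max_gap, lo, hi) {
  x <- hist$level
  rho <- hist$density
  phi_mid <- approx(attr(hist, "edges"), attr(hist, "phi_edges"), xout = x)$y
  Phi <- if (from_left) phi_mid else 1 - phi_mid
  D <- rep(1, length(x))
  masked <- hist$masked
  if (!is.null(diffusion)) {
    stopifnot(inherits(diffusion, "diffusion_profile"))
    if (nrow(diffusion) != nrow(hist) ||
        max(abs(diffusion$level - x)) > 1e-9 * max(1, diff(range(x))))
      abort("diffusion profile is on a different level grid")
    D <- diffusion$D
    masked <- masked | diffusion$masked | !is.finite(D)
  }
  inside <- x >= lo & x <= hi
  runs <- rle(masked & inside)
  bad <- runs$lengths > max_gap & runs$values
  if (any(bad)) {
    pos <- cumsum(runs$lengths)
    i <- which(bad)[1]
    abort(sprintf("masked gap of %d bins inside [%.4g, %.4g] near level %.4g",
                  runs$lengths[i], lo, hi, x[pos[i] - runs$lengths[i] + 1]))
  }
  if (sum(!masked & inside) < 2)
    abort("profile not sampled on enough levels between a and b")
  f <- ifelse(masked | rho <= 0, NA_real_, Phi / (D * rho))
  ok <- which(!is.na(f))
  if (any(is.na(f)))                       # bridge masked interior bins
    f <- approx(x[ok], f[ok], xout = x, rule = 2)$y
  list(mids = x, width = hist$width, f = f, edges = attr(hist, "edges"))
}

# integrate the per-bin integrand over [lo, hi] with partial end bins
kramers_sum <- function(ki, lo, hi) {
  e <- ki$edges
  nb <- length(ki$mids)
  covL <- pmin(e[-1], hi); covR <- pmax(e[-(nb + 1)], lo)
  cover <- pmax(0, covL - covR)
  sum(ki$f * cover)
}

#' Basin-averaged Kramers mean first passage time
#'
#' Equilibrium-weighted average of `mfpt(y0 -> b)` over start points `y0` on
#' the source side of the transition state.  The round-trip identity
#' `n_events = duration / (mfpt_fwd + mfpt_bwd)` requires cycle means, hence
#' this start convention for event-count estimation (point-start mfpt is
#' [kramers_mfpt()]).
#'
#' @inheritParams kramers_mfpt
#' @param x_ts transition-state level separating source from target side.
#' @param b absorbing target position.
#' @return basin-averaged mean first passage time.
#' @export
kramers_mfpt_basin <- function(hist, x_ts, b, diffusion = NULL, max_gap = 3) {
  stopifnot(inherits(hist, "hist_profile"))
  from_left <- x_ts < b
  x <- hist$level
  src <- if (from_left) which(x < x_ts & !hist$masked)
         else which(x > x_ts & !hist$masked)
  if (length(src) == 0) abort("no sampled source bins on that side of x_ts")
  w <- hist$density[src] * hist$width[src]
  w <- w / sum(w)
  ki <- kramers_bins(hist, diffusion, from_left, max_gap,
                     lo = min(x[src], b), hi = max(x[src], b))
  # mfpt(y0 -> b) = |M(b) - M(y0)| with M the running Kramers integral
  vals <- vapply(x[src], function(y0)
    kramers_sum(ki, min(y0, b), max(y0, b)), 1.0)
  sum(w * vals)
}

#' Estimated number of folding events over a trajectory
#'
#' Round trips per trajectory duration:
#' `n_events_est = duration / (mfpt_fwd + mfpt_bwd)`.  A sub-optimal
#' coordinate lowers the apparent barrier, shortens both mfpts, and
#' overestimates the event count — comparing this estimate with a direct
#' transition count ([count_transitions()]) is the coordinate-quality check.
#'
#' @param mfpt_fwd,mfpt_bwd forward / backward mean first passage times.
#' @param duration trajectory duration in the same time units.
#' @return estimated number of events.
#' @export
estimate_event_count <- function(mfpt_fwd, mfpt_bwd, duration) {
  if (mfpt_fwd <= 0 || mfpt_bwd <= 0 || duration <= 0)
    abort("mfpts and duration must be positive")
  duration / (mfpt_fwd + mfpt_bwd)
}

#' Direct transition count between basin cores
#'
#' Telegraph-filters the series with two thresholds: the state switches only
#' when the series enters the lower (`<= lower`) or upper (`>= upper`) core,
#' so barrier recrossings without full passage are not counted.
#'
#' @param series a [scalar_series()] or numeric vector.
#' @param lower,upper core thresholds, `lower < upper`.
#' @return a one-row tibble: `n_forward` (lower to upper passages),
#'   `n_backward`, `n_switches` (their sum).
#' @export
count_transitions <- function(series, lower, upper) {
  v <- if (inherits(series, "scalar_series")) series_values(series) else series
  if (lower >= upper) abort("need lower < upper")
  s <- integer(length(v))
  s[v <= lower] <- -1L
  s[v >= upper] <- 1L
  s <- s[s != 0L]
  if (length(s) < 2)
    return(tibble(n_forward = 0L, n_backward = 0L, n_switches = 0L))
  ch <- diff(s)
  tibble(n_forward = sum(ch == 2L), n_backward = sum(ch == -2L),
         n_switches = sum(ch != 0L))
}

#' Locate the transition state on a cut profile
#'
#' The transition state is the level of maximal cut free energy (minimal
#' `Z_C`) on the segment between the two deepest `F_C` minima; ties are
#' broken toward the midpoint of the tied plateau.  A profile without an
#' interior barrier between two basins is an error.
#'
#' @param cut a [cut_profile()].
#' @param basins optional list with `source` and `target` level intervals
#'   (each `c(lo, hi)`); the TS is then the `F_C` maximum between them.
#' @param native_value optional coordinate value of a reference (native)
#'   structure: the first basin is then the local `F_C` minimum reached
#'   downhill from that value rather than the global one, which keeps the
#'   located barrier pinned to the fold/unfold transition when the profile
#'   has additional shallow minima.
#' @param min_barrier smallest interior `F_C` rise (kT) counted as a real
#'   barrier in automatic mode; sampling wiggles on a barrier-less profile
#'   are well below 1 kT.
#' @return a `ts_location` list: `x_TS`, `F_TS`, `Z_C_TS`, basin levels
#'   `x_basins`, and their `F_C` values.
#' @export
locate_transition_state <- function(cut, basins = NULL, native_value = NULL,
                                    min_barrier = 1) {
  stopifnot(inherits(cut, "cut_profile"))
  ok <- !cut$masked
  x <- cut$level[ok]; fc <- cut$F_C[ok]
  if (length(x) < 3) abort("too few unmasked levels to locate a barrier")
  if (!is.null(basins)) {
    lo <- max(basins$source); hi <- min(basins$target)
    if (lo > hi) { tmp <- lo; lo <- max(basins$target); hi <- min(basins$source) }
    seg <- which(x > lo & x < hi)
    if (length(seg) == 0) abort("no levels between the basins")
    i_ts <- seg[tie_mid(fc[seg])]
    i1 <- which.min(abs(x - mean(basins$source)))
    i2 <- which.min(abs(x - mean(basins$target)))
  } else {
    i1 <- if (is.null(native_value)) which.min(fc)  # deepest basin
          else downhill_min(fc, which.min(abs(x - native_value)))
    # second basin: maximise the barrier seen from candidate j toward i1
    barrier_from <- vapply(seq_along(x), function(j) {
      if (j == i1) return(-Inf)
      seg <- seq(min(i1, j), max(i1, j))
      max(fc[seg]) - max(fc[i1], fc[j])
    }, 1.0)
    # among candidates with a real barrier, take the deepest second minimum
    cand <- which(barrier_from > min_barrier)
    if (length(cand) == 0) abort("barrier-less profile: no interior F_C maximum between basins")
    i2 <- cand[which.min(fc[cand])]
    seg <- seq(min(i1, i2), max(i1, i2))
    seg <- seg[seg != i1 & seg != i2]
    if (length(seg) == 0) abort("barrier-less profile: basins are adjacent levels")
    i_ts <- seg[tie_mid(fc[seg])]
  }
  xb <- c(x[i1], x[i2]); fb <- fc[c(i1, i2)]; ord <- order(xb)
  structure(list(x_TS = x[i_ts], F_TS = fc[i_ts],
                 Z_C_TS = exp(-fc[i_ts]),
                 x_basins = xb[ord], F_basins = fb[ord]),
            class = "ts_location")
}

# walk downhill on fc from index i to the local minimum of its basin
downhill_min <- function(fc, i) {
  repeat {
    if (i > 1 && fc[i - 1] < fc[i]) i <- i - 1
    else if (i < length(fc) && fc[i + 1] < fc[i]) i <- i + 1
    else return(i)
  }
}

# index of the maximum, ties broken toward the midpoint of the tied plateau
tie_mid <- function(fc) {
  mx <- max(fc)
  tied <- which(fc >= mx - 1e-12)
  tied[ceiling(length(tied) / 2)]
}

#' @export
print.ts_location <- function(x, ...) {
  cat(sprintf("<transition state at %.4g (F_C = %.3f kT), basins at %.4g / %.4g>\n",
              x$x_TS, x$F_TS, x$x_basins[1], x$x_basins[2]))
  invisible(x)
}

#' Full kinetics report for a projected series
#'
#' Pipeline: histogram + cut profiles, transition-state location, diffusion
#' profile, basin-averaged Kramers mfpts in both directions, and the
#' estimated event count, as written to the kinetics JSON report.
#'
#' @param series a [scalar_series()].
#' @param n_bins histogram bins.
#' @param k cut stride.
#' @param basins optional basin intervals for [locate_transition_state()].
#' @param native_value optional native-structure coordinate value pinning
#'   the first basin (see [locate_transition_state()]).
#' @return a `kinetics_result` list: `mfpt_forward`, `mfpt_backward`,
#'   `n_events_est`, `x_TS`, `F_C_TS`, `barrier_height_kT`, `duration`.
#' @export
kinetics_report <- function(series, n_bins = 32, k = 1, basins = NULL,
                            native_value = NULL) {
  series <- as_scalar_series(series)
  v <- series_values(series)
  # unit-width integer bins for integer-valued (contact) coordinates, so
  # bins and crossing levels stay aligned with the discrete values
  if (length(n_bins) == 1 && all(v == round(v)) && diff(range(v)) <= 512 &&
      diff(range(v)) >= 3)
    n_bins <- seq(min(v) - 0.5, max(v) + 0.5, by = 1)
  hist <- histogram_profile(series, n_bins)
  cut <- cut_profile(series, levels = hist$level, k = k)
  ts <- locate_transition_state(cut, basins, native_value)
  dp <- diffusion_profile(hist, cut)
  fwd <- kramers_mfpt_basin(hist, ts$x_TS, b = ts$x_basins[2], diffusion = dp)
  bwd <- kramers_mfpt_basin(hist, ts$x_TS, b = ts$x_basins[1], diffusion = dp)
  duration <- attr(hist, "n_frames") * series_dt(series)
  structure(list(mfpt_forward = fwd, mfpt_backward = bwd,
                 n_events_est = estimate_event_count(fwd, bwd, duration),
                 x_TS = ts$x_TS, F_C_TS = ts$F_TS,
                 barrier_height_kT = ts$F_TS - min(ts$F_basins),
                 duration = duration, n_bins = n_bins, k = k),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf(paste0("<kinetics: mfpt fwd %.4g / bwd %.4g, ",
                     "%.1f events estimated, TS at %.4g (barrier %.2f kT)>\n"),
              x$mfpt_forward, x$mfpt_backward, x$n_events_est, x$x_TS,
              x$barrier_height_kT))
  invisible(x)
}

#' @rdname kinetics_report
#' @param x a `kinetics_result`.
#' @param path output JSON path.
#' @export
write_kinetics <- function(x, path) {
  stopifnot(inherits(x, "kinetics_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
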