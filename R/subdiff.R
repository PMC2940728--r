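#' Coordinate-dependent anomalous-diffusion exponent
#'
#' The exponent `alpha(x)` describes how the mean absolute displacement
#' grows with the sampling interval (`MAD ~ dt^alpha`): 1/2 for diffusive
#' dynamics, below 1/2 for sub-diffusive, 1 for ballistic.  Because for a
#' fixed-length trajectory `Z_C(x; dt) ~ dt^(alpha - 1)`, the exponent
#' follows from cut profiles at two strides:
#' `alpha(x) = 1 + [ln Z_C(x; k2) - ln Z_C(x; k1)] / ln(k2 / k1)`,
#' and inherits the exact invariance of `Z_C` under strictly monotone
#' reparametrization.
#'
#' Standard errors (optional) come from a circular block bootstrap with
#' block length `10 x` the estimated correlation time, since crossing counts
#' are serially dependent.
#'
#' @param series a [scalar_series()].
#' @param levels level grid (default [level_grid()]).
#' @param k1,k2 the two strides, `k2 > k1 >= 1` (default 4 and 8; at very
#'   small strides the estimate probes the sub-sampling / inertial regime,
#'   so a warning is issued when the typical displacement over `k1` frames
#'   is below two grid spacings).
#' @param n_boot bootstrap replicates for standard errors (0 = skip).
#' @param block bootstrap block length in frames (default `10 x` estimated
#'   correlation time).
#' @return an `alpha_profile` tibble with columns `level`, `alpha`, `se`,
#'   `masked`; attributes `k1`, `k2`.
#' @export
alpha_profile <- function(series, levels = NULL, k1 = 4, k2 = 8,
                          n_boot = 0, block = NULL) {
  series <- as_scalar_series(series)
  if (k2 <= k1 || k1 < 1) abort("need k2 > k1 >= 1")
  v <- series_values(series)
  levels <- levels %||% level_grid(series)
  if (length(levels) > 1) {
    typ <- mean(abs(v[-seq_len(k1)] - v[seq_len(length(v) - k1)]))
    if (typ < 2 * median(diff(levels)))
      warn(sprintf(paste0("typical displacement over k1 = %d frames (%.3g) is ",
                          "below 2 grid spacings; alpha may be biased by ",
                          "discretization - consider larger strides"), k1, typ))
  }
  a <- alpha_at_levels(v, levels, k1, k2)
  se <- rep(NA_real_, length(levels))
  if (n_boot > 0) {
    block <- block %||% (10 * correlation_time(v))
    reps <- replicate(n_boot, {
      idx <- circular_block_sample(length(v), block)
      alpha_at_levels(v[idx], levels, k1, k2)
    })
    if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
    se <- apply(reps, 1, sd, na.rm = TRUE)
  }
  out <- new_profile_tibble(
    tibble(level = as.numeric(levels), alpha = a, se = se, masked = is.na(a)),
    "alpha_profile")
  attr(out, "k1") <- k1
  attr(out, "k2") <- k2
  out
}

alpha_at_levels <- function(v, levels, k1, k2) {
  z1 <- cpp_cut_counts(v, as.numeric(levels), as.integer(k1), TRUE) / (2 * k1)
  z2 <- cpp_cut_counts(v, as.numeric(levels), as.integer(k2), TRUE) / (2 * k2)
  ifelse(z1 > 0 & z2 > 0, 1 + (log(z2) - log(z1)) / log(k2 / k1), NA_real_)
}

# Integrated-autocorrelation-flavoured correlation time: first lag at which
# the autocorrelation of a subsampled copy drops below 1/e, in frames.
correlation_time <- function(v, max_lag = 1000) {
  n <- length(v)
  if (n > 2e5) { keep <- seq(1, n, by = ceiling(n / 2e5)); v <- v[keep] }
  ac <- stats::acf(v, lag.max = min(max_lag, length(v) - 2), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  tau <- which(ac < exp(-1))[1]
  if (is.na(tau)) tau <- length(ac)
  max(1, tau - 1) * max(1, ceiling(n / 2e5))
}

circular_block_sample <- function(n, block) {
  block <- max(1, min(round(block), n))
  starts <- sample.int(n, ceiling(n / block), replace = TRUE)
  idx <- as.vector(outer(0:(block - 1), starts - 1, `+`)) %% n + 1L
  idx[seq_len(n)]
}

#' Recommend a stride pair for the exponent estimate at a level
#'
#' Returns `(k, 2k)` for [alpha_profile()].  For continuous coordinates the
#' base sampling interval is already the unit of time and the smallest pair
#' `(1, 2)` is the most local choice.  Integer-valued (contact) coordinates
#' resolve displacements only in unit steps, which biases the exponent down
#' at strides whose typical displacement is below the value resolution: `k`
#' is the smallest power of two whose mean absolute displacement out of the
#' window `level +- 1/2` reaches 2 value units — or, when the displacement
#' saturates below that (narrow barriers), the smallest `k` within 10% of
#' the saturated displacement.
#'
#' @param series a [scalar_series()].
#' @param level the level (typically the transition state) at which the
#'   exponent will be estimated.
#' @param k_max largest base stride considered.
#' @return integer vector `c(k1, k2)`.
#' @export
recommend_strides <- function(series, level, k_max = 64) {
  series <- as_scalar_series(series)
  v <- series_values(series)
  if (!all(v == round(v))) return(c(1L, 2L))
  ks <- 2^(0:floor(log2(k_max)))
  origins <- which(abs(v - level) <= 0.5)
  if (length(origins) == 0) abort("no frames at that level")
  mads <- vapply(ks, function(k) {
    o <- origins[origins + k <= length(v)]
    mean(abs(v[o + k] - v[o]))
  }, 1.0)
  hit <- which(mads >= 2)
  k <- if (length(hit)) ks[hit[1]] else ks[which(mads >= 0.9 * max(mads))[1]]
  c(as.integer(k), 2L * as.integer(k))
}

#' Sampling-interval scan of the cut partition function at one level
#'
#' `Z_C(x*; k)` (offset-averaged) across strides at a fixed level, typically
#' the transition state: the sloped small-stride regime has slope
#' `alpha - 1` in log-log, and the large-stride plateau `Z_bal` counts
#' folding events (once the system crosses the barrier ballistically between
#' samples, no recrossings are detected).
#'
#' @param series a [scalar_series()].
#' @param level the level to scan (must lie inside the data range).
#' @param strides strictly increasing integer strides; the largest must stay
#'   below `n_frames / 10`.
#' @return a `cut_scan` tibble with columns `k`, `crossings`, `Z_C`;
#'   attributes `level`, `dt`.
#' @export
cut_scan <- function(series, level, strides = 2^(0:8)) {
  series <- as_scalar_series(series)
  v <- series_values(series)
  if (level < min(v) || level > max(v))
    abort(sprintf("level %.4g outside the data range [%.4g, %.4g]",
                  level, min(v), max(v)))
  strides <- as.integer(strides)
  if (any(diff(strides) <= 0) || any(strides < 1))
    abort("strides must be strictly increasing positive integers")
  if (max(strides) >= length(v) / 10)
    abort("largest stride must be < n_frames / 10")
  raw <- vapply(strides, function(k)
    cpp_cut_counts(v, level, k, TRUE)[1], 1.0)
  out <- new_profile_tibble(
    tibble(k = strides, crossings = raw, Z_C = raw / (2 * strides)),
    "cut_scan")
  attr(out, "level") <- level
  attr(out, "dt") <- series_dt(series)
  out
}

#' Two-line (sloped + plateau) fit of a cut-partition-function scan
#'
#' Approximates `ln Z_C(k)` by a sloped line `ln Z_bal + (alpha - 1) ln(k /
#' t_bal)` for `k < t_bal` joined continuously to the ballistic plateau
#' `ln Z_bal` for `k >= t_bal`.  The knee `t_bal` is the ballistic time; the
#' implied barrier width in natural-coordinate units is `w = t_bal^alpha`.
#' Strides beyond the dwell-time rolloff (first stride where `Z_C` drops 20%
#' below the running plateau median) are excluded, since the plateau decays
#' once strides approach the basin dwell time.
#'
#' Degenerate scans are flagged rather than forced: a flat scan returns
#' `regime = "plateau_only"` (alpha undefined); a scan entirely in the
#' sloped regime returns `regime = "sloped_only"` (knee undefined).
#'
#' @param scan a [cut_scan()].
#' @return a `ballistic_fit` list with elements `alpha`, `Z_bal`, `t_bal`,
#'   `w`, `dt0`, `regime`, `rss`, `fitted` (tibble of `k`, `Z_C`,
#'   `Z_C_fit`), `level`.
#' @export
fit_two_line <- function(scan) {
  stopifnot(inherits(scan, "cut_scan"))
  keep <- scan$Z_C > 0
  k <- scan$k[keep]; z <- scan$Z_C[keep]
  if (length(k) < 3) abort("need at least 3 strides with nonzero Z_C")
  # dwell-time rolloff: running median of the trailing half as plateau guess
  run_med <- vapply(seq_along(z), function(i) median(z[max(1, i - 2):i]), 1.0)
  roll <- which(z < 0.8 * cummax(run_med))
  if (length(roll) > 0 && roll[1] > 2) { k <- k[seq_len(roll[1] - 1)]; z <- z[seq_len(roll[1] - 1)] }
  lk <- log(k); lz <- log(z)
  n <- length(lk)
  two_line_rss <- function(lt) {
    s <- pmin(lk - lt, 0)                    # slope active below the knee
    fit <- stats::lm.fit(cbind(1, s), lz)
    sum(fit$residuals^2)
  }
  res <- list(level = attr(scan, "level"), dt0 = scan$k[1] * attr(scan, "dt"),
              scan_k = k, scan_z = z)
  if (sd(lz) < 1e-8) {
    fitv <- rep(exp(mean(lz)), n)
    return(finish_fit(res, alpha = NA_real_, z_bal = exp(mean(lz)),
                      t_bal = NA_real_, regime = "plateau_only",
                      k = k, z = z, fitv = fitv))
  }
  lo <- min(lk); hi <- max(lk)
  opt <- optimise(two_line_rss, c(lo, hi))
  lt <- opt$minimum
  edge_tol <- 0.02 * (hi - lo)
  if (lt >= hi - edge_tol) {                 # pure sloped regime
    fit <- lm(lz ~ lk)
    alpha <- 1 + coef(fit)[[2]]
    return(finish_fit(res, alpha = alpha, z_bal = NA_real_, t_bal = NA_real_,
                      regime = "sloped_only", k = k, z = z,
                      fitv = exp(stats::fitted(fit))))
  }
  if (lt <= lo + edge_tol) {
    fitv <- rep(exp(mean(lz)), n)
    return(finish_fit(res, alpha = NA_real_, z_bal = exp(mean(lz)),
                      t_bal = NA_real_, regime = "plateau_only",
                      k = k, z = z, fitv = fitv))
  }
  s <- pmin(lk - lt, 0)
  fit <- stats::lm.fit(cbind(1, s), lz)
  alpha <- 1 + fit$coefficients[2]
  if (sum(lk < lt) < 3 || sum(lk >= lt) < 3)
    warn("fewer than 3 strides on one side of the knee; fit is poorly constrained")
  finish_fit(res, alpha = alpha, z_bal = exp(fit$coefficients[1]),
             t_bal = exp(lt), regime = "two_line", k = k, z = z,
             fitv = exp(fit$coefficients[1] + alpha_slope(alpha) * s))
}

alpha_slope <- function(alpha) alpha - 1

finish_fit <- function(res, alpha, z_bal, t_bal, regime, k, z, fitv) {
  structure(list(alpha = unname(alpha), Z_bal = unname(z_bal),
                 t_bal = unname(t_bal),
                 w = if (is.na(t_bal) || is.na(alpha)) NA_real_
                     else unname(t_bal^alpha),
                 dt0 = res$dt0, level = res$level, regime = regime,
                 rss = sum((log(z) - log(fitv))^2),
                 fitted = tibble(k = k, Z_C = z, Z_C_fit = fitv)),
            class = "ballistic_fit")
}

#' @export
print.ballistic_fit <- function(x, ...) {
  cat(sprintf("<ballistic_fit: regime %s, alpha = %.3f, Z_bal = %.4g, t_bal = %.4g>\n",
              x$regime, x$alpha, x$Z_bal, x$t_bal))
  invisible(x)
}

#' Closed-form exponent from the two-line ballistic model
#'
#' Given the cut free energy at the transition state `F_ts = -ln Z_C(TS)`
#' (base stride), the ballistic plateau `Z_bal` (number of folding events)
#' and the ballistic time `t_bal`, the two straight lines of the scan
#' determine the exponent:
#' `alpha = 1 - [(-F_ts) - ln Z_bal] / ln(t_bal / dt0)`,
#' equivalently `alpha = ln w / (ln w + dF)` with `dF = (-F_ts) - ln Z_bal`
#' and barrier width `w = t_bal^alpha`.  Higher cut free-energy barriers give
#' exponents closer to 1/2 (diffusive); `alpha > 1` signals over-fitting of
#' the trajectory by the coordinate and triggers a warning.
#'
#' @param F_ts cut free energy at the transition state, kT (negative for a
#'   well-sampled barrier: `-F_ts = ln Z_C(TS)`).
#' @param Z_bal ballistic plateau, events.
#' @param t_bal ballistic time, time units.
#' @param dt0 base sampling interval (default 1).
#' @return a one-row tibble with `alpha`, `w` (implied barrier width,
#'   natural-coordinate units) and `delta_F = (-F_ts) - ln Z_bal`.
#' @export
#' @examples
#' alpha_from_barrier(-9.72, 100, 1924)$alpha   # about 0.32
alpha_from_barrier <- function(F_ts, Z_bal, t_bal, dt0 = 1) {
  if (any(t_bal <= dt0)) abort("t_bal must exceed dt0")
  if (any(Z_bal <= 0)) abort("Z_bal must be > 0")
  delta_F <- (-F_ts) - log(Z_bal)
  alpha <- 1 - delta_F / log(t_bal / dt0)
  if (any(delta_F < 0))
    warn("(-F_ts) < ln Z_bal: alpha > 1 (superdiffusion) indicates over-fitting")
  tibble(alpha = alpha, w = t_bal^alpha, delta_F = delta_F)
}

#' Mean square displacement from windowed origins
#'
#' MSD and mean absolute displacement over lag `tau`, averaged over every
#' frame whose value lies in `[level - half_width, level + half_width]`
#' (pieces of the trajectory launched from, e.g., the transition state).
#' Exponents `gamma` (MSD ~ tau^gamma) and `alpha` (MAD ~ tau^alpha) are
#' fitted by log-log regression over `fit_range`.  Compute this on the
#' natural coordinate if a diffusive reference slope of `2 tau` (D = 1) is
#' wanted.
#'
#' @param series a [scalar_series()] (typically the natural coordinate).
#' @param level window centre.
#' @param half_width window half width.
#' @param max_lag largest lag, frames.
#' @param n_lags number of log-spaced lags.
#' @param fit_range lag range (inclusive) for the exponent fits; default
#'   `c(1, max_lag / 4)`.
#' @param max_origins cap on origins used (deterministic thinning).
#' @return an `msd_curve` tibble with columns `lag`, `time`, `msd`, `mad`,
#'   `n_pairs`; attributes `n_origins`, `gamma`, `alpha`, `level`,
#'   `half_width`, `fit_range`.
#' @export
msd_from_window <- function(series, level, half_width, max_lag = 1000,
                            n_lags = 40, fit_range = NULL,
                            max_origins = 2e5) {
  series <- as_scalar_series(series)
  v <- series_values(series)
  n <- length(v)
  if (max_lag >= n) abort("max_lag must be below the series length")
  origins <- which(abs(v - level) <= half_width)
  if (length(origins) == 0) abort("no origins in the window")
  if (length(origins) < 50)
    warn(sprintf("only %d origins in the window; MSD will be noisy",
                 length(origins)))
  if (length(origins) > max_origins)
    origins <- origins[seq(1, length(origins),
                           by = ceiling(length(origins) / max_origins))]
  lags <- unique(round(exp(seq(log(1), log(max_lag), length.out = n_lags))))
  msd <- mad_ <- np <- numeric(length(lags))
  for (i in seq_along(lags)) {
    tau <- lags[i]
    o <- origins[origins + tau <= n]
    if (length(o) == 0) { msd[i] <- NA; mad_[i] <- NA; np[i] <- 0; next }
    d <- v[o + tau] - v[o]
    msd[i] <- mean(d * d); mad_[i] <- mean(abs(d)); np[i] <- length(o)
  }
  fit_range <- fit_range %||% c(1, max(2, max_lag / 4))
  sel <- lags >= fit_range[1] & lags <= fit_range[2] & !is.na(msd) & msd > 0
  gamma <- alpha <- NA_real_
  if (sum(sel) >= 2) {
    gamma <- coef(lm(log(msd[sel]) ~ log(lags[sel])))[[2]]
    alpha <- coef(lm(log(mad_[sel]) ~ log(lags[sel])))[[2]]
  }
  out <- new_profile_tibble(
    tibble(lag = lags, time = lags * series_dt(series), msd = msd,
           mad = mad_, n_pairs = np),
    "msd_curve")
  attr(out, "n_origins") <- length(origins)
  attr(out, "gamma") <- gamma
  attr(out, "alpha") <- alpha
  attr(out, "level") <- level
  attr(out, "half_width") <- half_width
  attr(out, "fit_range") <- fit_range
  out
}
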