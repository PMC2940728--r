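#' Exact fractional Brownian motion
#'
#' Generates fBm sampled at unit spacing with covariance
#' `Cov(B_s, B_t) = scale^2 / 2 * (s^(2H) + t^(2H) - |t - s|^(2H))`
#' by circulant embedding of the increment (fractional Gaussian noise)
#' covariance (Davies-Harte), which is exact when the embedding is
#' nonnegative definite.  For small `n` a dense Cholesky factorization of the
#' fBm covariance is available as `method = "cholesky"` and serves as the
#' fallback if the embedding fails; failure at large `n` is an error, never a
#' silent approximation.
#'
#' `hurst = 0.5` gives ordinary Brownian motion; `hurst < 0.5` is the
#' sub-diffusive reference process whose anomalous exponent equals `hurst`.
#'
#' @param hurst Hurst exponent in (0, 1).
#' @param n_steps number of unit-spaced samples.
#' @param scale length per unit time^hurst.
#' @param seed integer seed or `NULL`.
#' @return `simulate_fbm()` returns a [scalar_series()] of `B_1 ... B_n`
#'   (dt = 1).
#' @export
#' @examples
#' b <- simulate_fbm(fbm_config(0.25, 1024, seed = 1))
fbm_config <- function(hurst, n_steps, scale = 1, seed = NULL) {
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1)
    abort("hurst must be in (0, 1)")
  if (n_steps < 2) abort("n_steps must be >= 2")
  if (scale <= 0) abort("scale must be > 0")
  structure(list(hurst = hurst, n_steps = as.integer(n_steps), scale = scale,
                 seed = seed), class = "fbm_config")
}

#' @rdname fbm_config
#' @param config an `fbm_config`.
#' @param method `"circulant"` (default; exact Davies-Harte embedding) or
#'   `"cholesky"` (dense factorization, n <= 4096).
#' @export
simulate_fbm <- function(config, method = c("circulant", "cholesky")) {
  stopifnot(inherits(config, "fbm_config"))
  method <- match.arg(method)
  n <- config$n_steps; H <- config$hurst
  with_seed(config$seed, {
    incr <- switch(method,
      circulant = fgn_davies_harte(n, H),
      cholesky = fbm_cholesky_increments(n, H))
    scalar_series(cumsum(incr) * config$scale, dt = 1,
                  provenance = list(generator = "fbm", hurst = H,
                                    scale = config$scale,
                                    seed = config$seed %||% NA,
                                    method = method))
  })
}

# fGn autocovariance at integer lags (unit-variance increments).
fgn_acov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Davies-Harte: exact fGn of length n via circulant embedding of size 2n.
fgn_davies_harte <- function(n, H) {
  m <- 2L * n
  row <- fgn_acov(c(0:n, (n - 1):1), H)
  lam <- Re(fft(row))
  tol <- 1e-10 * max(lam)
  if (min(lam) < -tol) {
    if (n <= 4096) return(fbm_cholesky_increments(n, H))
    abort(sprintf(paste0("circulant embedding not nonnegative definite ",
                         "(min eigenvalue %.3g) and n = %d too large for the ",
                         "dense fallback"), min(lam), n))
  }
  lam[lam < 0] <- 0
  v <- complex(length.out = m)
  v[1] <- sqrt(lam[1]) * rnorm(1)
  v[n + 1] <- sqrt(lam[n + 1]) * rnorm(1)
  zr <- rnorm(n - 1); zi <- rnorm(n - 1)
  v[2:n] <- sqrt(lam[2:n] / 2) * complex(real = zr, imaginary = zi)
  v[m:(n + 2)] <- Conj(v[2:n])
  Re(fft(v))[1:n] / sqrt(m)
}

# Dense route: factor the fBm covariance itself, return increments.
fbm_cholesky_increments <- function(n, H) {
  if (n > 4096) abort("cholesky method limited to n <= 4096")
  t <- seq_len(n)
  sigma <- 0.5 * (outer(t^(2 * H), t^(2 * H), `+`) -
                    abs(outer(t, t, `-`))^(2 * H))
  b <- drop(t(chol(sigma)) %*% rnorm(n))
  diff(c(0, b))
}

#' Closed-form fBm covariance matrix
#'
#' `Cov(B_s, B_t)` for `s, t = 1..n` at unit spacing and `scale = 1`; used as
#' the independent oracle for the generators.
#'
#' @inheritParams fbm_config
#' @param n number of samples.
#' @return an `n x n` covariance matrix.
#' @export
fbm_covariance <- function(n, hurst) {
  t <- seq_len(n)
  0.5 * (outer(t^(2 * hurst), t^(2 * hurst), `+`) -
           abs(outer(t, t, `-`))^(2 * hurst))
}
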