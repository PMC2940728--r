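#' Overdamped Langevin dynamics on a quartic double well
#'
#' Simulates `y' = -dU/dy + sqrt(2 D) xi(t)` with Euler-Maruyama on the
#' quartic potential
#' `U(y) = barrier_height * ((2 y / well_separation)^2 - 1)^2` (kT = 1),
#' which has minima at `+/- well_separation / 2` and barrier top at 0.
#' This is the diffusive reference process: its projection onto itself is
#' exactly diffusive, so the anomalous exponent at the barrier top must come
#' out 1/2.
#'
#' `doublewell_config()` validates parameters at construction, including the
#' step-size sanity check `dt_integrate * max|F| < well_separation / 10`
#' (drift displacement per step small against the landscape; `max|F|` is
#' taken over `|y| <= well_separation`).
#'
#' @param barrier_height barrier in kT (>= 0; 0 gives free diffusion).
#' @param well_separation distance between minima, natural length units.
#' @param diffusion_coeff D, length^2 / time.
#' @param n_steps number of Euler steps (saved frames = `n_steps / save_stride`).
#' @param dt_integrate integration time step.
#' @param save_stride Euler steps per saved frame; the saved spacing
#'   `dt_integrate * save_stride` is recorded on the series.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param y0 initial position (default: left minimum, or 0 when flat).
#' @return `simulate_doublewell()` returns a [scalar_series()] of saved frames.
#' @export
#' @examples
#' s <- simulate_doublewell(doublewell_config(4, n_steps = 1e4,
#'                                            dt_integrate = 1e-3, seed = 1))
doublewell_config <- function(barrier_height, well_separation = 2,
                              diffusion_coeff = 1, n_steps = 1e6,
                              dt_integrate = 1e-3, save_stride = 1,
                              seed = NULL, y0 = NULL) {
  if (barrier_height < 0) abort("barrier_height must be >= 0")
  if (well_separation <= 0) abort("well_separation must be > 0")
  if (diffusion_coeff <= 0) abort("diffusion_coeff must be > 0")
  if (n_steps < 1) abort("n_steps must be >= 1")
  if (save_stride < 1 || save_stride != round(save_stride))
    abort("save_stride must be a positive integer")
  # max drift magnitude of the quartic on |y| <= well_separation is 48 h / sep
  fmax <- 48 * barrier_height / well_separation
  if (dt_integrate * fmax >= well_separation / 10)
    abort(sprintf(paste0("dt_integrate too large: dt * max|F| = %.3g must be ",
                         "< well_separation/10 = %.3g"),
                  dt_integrate * fmax, well_separation / 10))
  structure(list(barrier_height = barrier_height,
                 well_separation = well_separation,
                 diffusion_coeff = diffusion_coeff, n_steps = n_steps,
                 dt_integrate = dt_integrate, save_stride = save_stride,
                 seed = seed,
                 y0 = y0 %||% if (barrier_height > 0) -well_separation / 2 else 0),
            class = "doublewell_config")
}

#' @rdname doublewell_config
#' @param config a `doublewell_config`.
#' @export
simulate_doublewell <- function(config) {
  stopifnot(inherits(config, "doublewell_config"))
  with_seed(config$seed, {
    vals <- cpp_simulate_doublewell(config$barrier_height,
                                    config$well_separation,
                                    config$diffusion_coeff,
                                    config$n_steps, config$dt_integrate,
                                    as.integer(config$save_stride), config$y0)
    scalar_series(vals, dt = config$dt_integrate * config$save_stride,
                  provenance = list(generator = "doublewell",
                                    barrier_height = config$barrier_height,
                                    well_separation = config$well_separation,
                                    diffusion_coeff = config$diffusion_coeff,
                                    seed = config$seed %||% NA))
  })
}

#' Quartic double-well potential
#'
#' @param y position(s).
#' @param barrier_height barrier in kT.
#' @param well_separation distance between minima.
#' @return potential energy in kT.
#' @export
doublewell_potential <- function(y, barrier_height, well_separation = 2) {
  barrier_height * ((2 * y / well_separation)^2 - 1)^2
}

#' Direct first-passage-time sampling on the quartic double well
#'
#' Simulates independent passages from `a` until first crossing of `b`,
#' returning the elapsed times; the empirical mean is an independent check on
#' the Kramers mean-first-passage-time quadrature.
#'
#' @inheritParams doublewell_config
#' @param a,b start and target positions.
#' @param n_events number of passages to sample.
#' @param max_steps total Euler-step budget across all events.
#' @return numeric vector of `n_events` first-passage times.
#' @export
sample_first_passage <- function(barrier_height, well_separation = 2,
                                 diffusion_coeff = 1, dt_integrate = 1e-3,
                                 a = -well_separation / 2,
                                 b = well_separation / 2,
                                 n_events = 100, max_steps = 1e9,
                                 seed = NULL) {
  with_seed(seed,
    cpp_first_passage(barrier_height, well_separation, diffusion_coeff,
                      dt_integrate, a, b, as.integer(n_events), max_steps))
}

# Evaluate expr with a locally-set seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(expr)
}
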