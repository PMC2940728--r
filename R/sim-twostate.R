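#' Two-state atomistic toy trajectories with a known latent folding coordinate
#'
#' Emulates the statistical structure of an equilibrium folding trajectory at
#' desk scale: a hidden folding coordinate `s(t)` (overdamped Langevin on a
#' double well, of order 10^2 barrier crossings at the defaults) drives
#' interpolation between two reference structures, with stationary
#' Ornstein-Uhlenbeck positional noise per atom coordinate so that
#' projections on poorly chosen coordinates retain memory (the sub-optimal
#' projection phenomenology).  Frame `t` is
#' `(1 - sigma_t) A + sigma_t B + eta(t)` with
#' `sigma_t = logistic(s(t) / switch_width)`.
#'
#' Defaults: 8 atoms (the packaged toy structures, pairwise distance changes
#' spanning roughly 0.5-12 Angstrom), latent barrier 4 kT, 10^6 saved frames,
#' noise amplitude 0.5 Angstrom with correlation time 5 frames, seed 7.
#'
#' @param struct_a,struct_b reference `M x 3` coordinate matrices (Angstrom);
#'   defaults to [toy_structures()].
#' @param latent a [doublewell_config()] for the hidden coordinate; its `seed`
#'   is ignored (the generator's own `seed` governs the full stream).
#' @param switch_width latent-coordinate units over which the interpolation
#'   weight goes through its logistic switch.
#' @param noise_amp stationary per-atom, per-dimension noise sd (Angstrom).
#' @param noise_corr_time noise correlation time, frame units.
#' @param seed integer seed or `NULL`.
#' @return `simulate_two_state_atoms()` returns
#'   `list(trajectory = atom_trajectory, latent = scalar_series)`; the latent
#'   series is the ground truth every coordinate is judged against.
#' @export
#' @examples
#' cfg <- twostate_config(latent = doublewell_config(4, n_steps = 5e4,
#'                        dt_integrate = 2e-3, save_stride = 5))
#' out <- simulate_two_state_atoms(cfg)
twostate_config <- function(struct_a = toy_structures()$a,
                            struct_b = toy_structures()$b,
                            latent = doublewell_config(
                              barrier_height = 4, well_separation = 2,
                              diffusion_coeff = 1, n_steps = 3e6,
                              dt_integrate = 1e-3, save_stride = 3),
                            switch_width = 0.25, noise_amp = 0.5,
                            noise_corr_time = 5, seed = 7) {
  struct_a <- as.matrix(struct_a); struct_b <- as.matrix(struct_b)
  if (!identical(dim(struct_a), dim(struct_b)))
    abort("struct_a and struct_b must have identical dimensions")
  if (ncol(struct_a) != 3) abort("structures must be M x 3 matrices")
  if (switch_width <= 0) abort("switch_width must be > 0")
  if (noise_amp < 0) abort("noise_amp must be >= 0")
  if (noise_corr_time <= 0) abort("noise_corr_time must be > 0")
  stopifnot(inherits(latent, "doublewell_config"))
  structure(list(struct_a = struct_a, struct_b = struct_b, latent = latent,
                 switch_width = switch_width, noise_amp = noise_amp,
                 noise_corr_time = noise_corr_time, seed = seed),
            class = "twostate_config")
}

#' @rdname twostate_config
#' @param config a `twostate_config`.
#' @export
simulate_two_state_atoms <- function(config) {
  stopifnot(inherits(config, "twostate_config"))
  with_seed(config$seed, {
    lat_cfg <- config$latent
    lat_cfg$seed <- NULL
    latent <- simulate_doublewell(lat_cfg)
    s <- series_values(latent)
    n <- length(s); m <- nrow(config$struct_a)
    sigma <- stats::plogis(s / config$switch_width)
    coords <- array(NA_real_, c(n, m, 3))
    for (d in 1:3)
      coords[, , d] <- outer(1 - sigma, config$struct_a[, d]) +
        outer(sigma, config$struct_b[, d])
    if (config$noise_amp > 0) {
      rho <- exp(-1 / config$noise_corr_time)
      si <- config$noise_amp * sqrt(1 - rho^2)
      for (a in seq_len(m)) for (d in 1:3) {
        innov <- rnorm(n) * si
        innov[1] <- rnorm(1) * config$noise_amp   # stationary start
        coords[, a, d] <- coords[, a, d] +
          as.numeric(stats::filter(innov, rho, method = "recursive"))
      }
    }
    attr(latent, "provenance")$generator <- "twostate_latent"
    attr(latent, "provenance")$seed <- config$seed %||% NA
    list(trajectory = atom_trajectory(coords, frame_spacing = 1),
         latent = latent)
  })
}

#' Packaged toy reference structures
#'
#' Two 8-atom configurations — a compact helical arrangement (`a`) and an
#' extended chain (`b`) — whose pairwise distance changes span roughly
#' 0.5 to 12 Angstrom, so contact- and distance-based coordinates have a
#' usable signal range.  Coordinates are frozen constants; the same values
#' ship as PDB/XYZ fixtures under `inst/extdata/`.
#'
#' @return `list(a = , b = )` of `8 x 3` matrices (Angstrom).
#' @export
toy_structures <- function() {
  a <- matrix(c(
     3.000,  0.000, 0.0,
    -0.521,  2.954, 1.1,
    -2.819, -1.026, 2.2,
     1.500, -2.598, 3.3,
     2.298,  1.928, 4.4,
    -2.298,  1.928, 5.5,
    -1.500, -2.598, 6.6,
     2.819, -1.026, 7.7), ncol = 3, byrow = TRUE)
  b <- cbind(rep(0, 8), rep(0, 8), 2.8 * (0:7))
  list(a = a, b = b)
}
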