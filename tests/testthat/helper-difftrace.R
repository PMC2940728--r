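# Brute-force O(N x levels) crossing-count oracle, independent of the
# package's difference-array kernel.  Tie rule: frames at a level sit left.
brute_cut_counts <- function(v, levels, k, all_phases = TRUE) {
  ts <- if (all_phases) seq_len(length(v) - k) else
    seq(1, length(v) - k, by = k)
  vapply(levels, function(l) {
    sum((v[ts] <= l) != (v[ts + k] <= l))
  }, 1.0)
}

# small two-state simulation shared by optimizer tests (kept modest so the
# suite stays fast; the full-scale run lives in the acceptance tests)
make_small_twostate <- function(n_frames = 2e5, noise_amp = 0.5, seed = 7) {
  cfg <- twostate_config(
    latent = doublewell_config(4, 2, 1, n_steps = 3 * n_frames,
                               dt_integrate = 1e-3, save_stride = 3),
    noise_amp = noise_amp, seed = seed)
  simulate_two_state_atoms(cfg)
}

# Brownian (free diffusion) series with D = 1 in frame units
brownian_series <- function(n, D = 1, seed = 1) {
  set.seed(seed)
  scalar_series(cumsum(rnorm(n, sd = sqrt(2 * D))))
}

# two-state telegraph series with exponential dwell times
telegraph_series <- function(n_dwells = 400, mean_dwell = 1000, seed = 9) {
  set.seed(seed)
  dw <- pmax(1, round(rexp(n_dwells, 1 / mean_dwell)))
  scalar_series(rep(rep(c(0, 1), length.out = n_dwells), times = dw))
}

# synthetic cut_scan with the package's class/attribute layout
fake_cut_scan <- function(k, z, level = 0, dt = 1) {
  sc <- tibble::tibble(k = as.integer(k), crossings = z * 2 * k, Z_C = z)
  class(sc) <- c("cut_scan", class(tibble::tibble()))
  attr(sc, "level") <- level
  attr(sc, "dt") <- dt
  sc
}
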