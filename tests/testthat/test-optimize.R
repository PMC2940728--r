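# shared small two-state system (2e5 frames, ~20 events)
two <- make_small_twostate(n_frames = 2e5, seed = 7)
A <- toy_structures()$a
nnc <- native_contact_init(A, cutoff = 7)
scrambled <- scramble_signs(nnc, seed = 99)

test_that("objective pipeline recovers the flat closed form and invariance", {
  set.seed(4)
  D <- 5e-5
  x <- cumsum(rnorm(1e6, sd = sqrt(2 * D)))
  refl <- scalar_series(abs(((x + 1) %% 2) - 1))  # Brownian on [0, 1]
  ob <- objective_mfpt(refl)
  expect_true(ob$flagged)                         # barrier-less, flagged
  expect_equal(ob$value, 1 / (2 * D), tolerance = 0.1)

  s <- simulate_doublewell(doublewell_config(4, 2, 1, n_steps = 1e6,
                                             dt_integrate = 1e-3,
                                             save_stride = 2, seed = 3))
  o1 <- objective_mfpt(s)
  o2 <- objective_mfpt(scalar_series(series_values(s)^3 + 2,
                                     dt = series_dt(s)))
  expect_equal(o2$value, o1$value, tolerance = 1e-12)
  expect_error(objective_mfpt(scalar_series(rep(1, 10) + 0:9 * 0)),
               "degenerate")
})

test_that("the ground-truth coordinate outranks a scrambled one", {
  lat <- scalar_series(series_values(two$latent))   # frame time units
  o_lat <- objective_mfpt(lat)
  o_scr <- objective_mfpt(eval_coordinate(two$trajectory, scrambled))
  expect_gt(o_lat$value, o_scr$value)
})

test_that("an exactly representable latent gives the latent's objective", {
  noiseless <- make_small_twostate(n_frames = 2e5, noise_amp = 0, seed = 7)
  q2 <- eval_coordinate(noiseless$trajectory, distance_spec(rbind(c(0, 7)), 1))
  o_q2 <- objective_mfpt(q2)
  o_lat <- objective_mfpt(scalar_series(series_values(noiseless$latent)))
  expect_equal(o_q2$value, o_lat$value, tolerance = 0.05)
})

test_that("accepted objectives increase strictly and runs replay exactly", {
  cfg <- optimizer_config(n_sweeps = 1, seed = 5)
  tr <- optimize_coordinate(two$trajectory, scrambled, cfg, native = A)
  expect_gt(nrow(tr$steps), 0)
  expect_true(all(diff(tr$steps$objective) > 0))
  expect_gte(tr$objective_final, tr$objective_init)
  tr2 <- optimize_coordinate(two$trajectory, scrambled, cfg, native = A)
  expect_identical(tr$steps, tr2$steps)
  expect_identical(tr$best_spec, tr2$best_spec)
  # trace serializes
  p <- withr::local_tempfile(fileext = ".json")
  write_opt_trace(tr, p)
  expect_true(jsonlite::validate(paste(readLines(p), collapse = "\n")))
  expect_equal(glance(tr)$n_accepted, nrow(tr$steps))
  expect_identical(tidy(tr), tr$steps)
})

test_that("a stall-converged coordinate on a small family is a fixed point", {
  pairs3 <- rbind(c(0L, 7L), c(0L, 6L), c(1L, 7L))
  init <- contact_spec(pairs3, signs = c(1, 1, 1), thresholds = c(12, 10, 12))
  cfg <- optimizer_config(n_sweeps = 12, seed = 11, candidate_pairs = pairs3,
                          stall_limit = 30)
  tr <- optimize_coordinate(two$trajectory, init, cfg, native = A)
  # contact evaluation is integer-exact and the per-pair grids are
  # deterministic, so rescanning the converged spec cannot improve it
  tr2 <- optimize_coordinate(two$trajectory, tr$best_spec,
                             optimizer_config(n_sweeps = 2, seed = 99,
                                              candidate_pairs = pairs3),
                             native = A)
  expect_equal(nrow(tr2$steps), 0)
  expect_equal(tr2$objective_final, tr2$objective_init)
})

test_that("degenerate candidates are skipped with a log entry, not evaluated", {
  # a 3-frame-valued trajectory where extreme thresholds yield constants
  frames <- array(0, c(100, 2, 3))
  frames[, 2, 1] <- rep(c(3, 6), 50)
  tr <- atom_trajectory(frames)
  spec <- contact_spec(rbind(c(0, 1)), 1, 5)
  expect_error(
    optimize_coordinate(tr, spec, optimizer_config(n_sweeps = 1, seed = 1)),
    "not computable|constant")
})

test_that("over-parameterized fits on short data trigger superdiffusion flags", {
  n_flagged <- 0L
  for (seed in 1:3) {
    toy <- make_small_twostate(n_frames = 1e4, seed = seed)
    tr <- optimize_coordinate(toy$trajectory,
                              distance_spec(rbind(c(0, 7)), 1),
                              optimizer_config(n_sweeps = 2, seed = seed + 50))
    qb <- eval_coordinate(toy$trajectory, tr$best_spec)
    rep <- suppressWarnings(diagnose_overfit(tr, qb, k1 = 1, k2 = 2,
                                             n_boot = 20))
    if (nrow(rep$flags) > 0) n_flagged <- n_flagged + 1L
  }
  # regression guard: the majority of short-trajectory fits must over-fit
  expect_gte(n_flagged, 2L)
})

test_that("the diffusive ground-truth coordinate is not flagged at its TS", {
  lat <- scalar_series(series_values(two$latent))
  rep <- suppressWarnings(diagnose_overfit(NULL, lat, k1 = 1, k2 = 2,
                                           n_boot = 20))
  expect_false(is.na(rep$alpha_ts))
  expect_lt(rep$alpha_ts, 0.5 + 2 * rep$se_ts)
  empty <- diagnose_overfit(NULL, NULL)
  expect_equal(nrow(empty$flags), 0)
})

test_that("min_crossings objective ranks coordinates like mfpt", {
  lat <- scalar_series(series_values(two$latent))
  o_lat <- objective_mfpt(lat, objective = "min_crossings")
  o_scr <- objective_mfpt(eval_coordinate(two$trajectory, scrambled),
                          objective = "min_crossings")
  expect_gt(o_lat$value, o_scr$value)
})
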