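test_that("flat profile gives the L^2/2 closed form", {
  v <- rep(seq(0.0005, 0.9995, length.out = 1000), times = 100)
  h <- histogram_profile(scalar_series(v), 50)
  expect_equal(kramers_mfpt(h, 0, 1), 0.5, tolerance = 2e-3)
  expect_equal(kramers_mfpt(h, 0, 0), 0)
  expect_error(kramers_mfpt(h, -0.5, 1), "support")
})

test_that("quartic barrier mfpt matches two independent oracles", {
  U <- function(y) doublewell_potential(y, 4, 2)
  bp <- boltzmann_profile(U, c(-1.8, 1.8), n_bins = 400)
  m <- kramers_mfpt(bp, -1, 1)
  # dense-grid double-integral oracle
  inner <- Vectorize(function(y) integrate(function(z) exp(-U(z)), -1.8, y)$value)
  oracle <- integrate(function(y) exp(U(y)) * inner(y), -1, 1)$value
  expect_equal(m, oracle, tolerance = 0.02)
  # direct first-passage simulation
  fp <- sample_first_passage(4, 2, 1, dt_integrate = 5e-4, n_events = 200,
                             seed = 5)
  expect_equal(m, mean(fp), tolerance = 0.15)
})

test_that("masked interior gaps abort the quadrature with a location", {
  v <- c(runif(5000, 0, 1), runif(5000, 2, 3))   # hole in (1, 2)
  set.seed(1)
  h <- histogram_profile(scalar_series(v), 30)
  expect_error(kramers_mfpt(h, 0.2, 2.8), "masked gap")
})

test_that("event-count estimation is round trips per duration", {
  expect_equal(estimate_event_count(4e3, 1e3, 1e6), 200)
  expect_equal(estimate_event_count(500, 500, 1e4), 10)
  expect_error(estimate_event_count(-1, 1, 1), "positive")
})

test_that("transition counting telegraph-filters recrossings", {
  v <- c(0, 0.6, 0.4, 1, 0.55, 0.45, 0, 1, 0)
  tr <- count_transitions(v, 0.25, 0.75)
  expect_equal(tr$n_forward, 2)
  expect_equal(tr$n_backward, 2)
  expect_equal(tr$n_switches, 4)
})

test_that("transition state sits at the F_C maximum between basins", {
  lv <- seq(0.05, 0.95, by = 0.05)
  zc <- 1e3 * exp(-((lv - 0.5)^2) * 8)       # Z_C peaked -> F_C dipped
  zc <- 1e3 * exp(+((lv - 0.5)^2) * 8)       # F_C peaked at 0.5
  cp <- tibble::tibble(level = lv, crossings = 2 * zc, Z_C = zc,
                       F_C = -log(zc), masked = FALSE)
  class(cp) <- c("cut_profile", class(tibble::tibble()))
  attr(cp, "k") <- 1
  ts <- locate_transition_state(cp)
  expect_equal(ts$x_TS, 0.5)

  flat <- cp; flat$Z_C <- rep(10, length(lv)); flat$F_C <- -log(flat$Z_C)
  expect_error(locate_transition_state(flat), "barrier-less")
})

test_that("double-well simulation puts the transition state at the saddle", {
  s <- simulate_doublewell(doublewell_config(4, 2, 1, n_steps = 4e6,
                                             dt_integrate = 1e-3,
                                             save_stride = 4, seed = 13))
  h <- histogram_profile(s, 32)
  cp <- cut_profile(s, levels = h$level, k = 1)
  ts <- locate_transition_state(cp)
  expect_lt(abs(ts$x_TS - 0), median(h$width) * 1.5)
  expect_equal(sort(sign(ts$x_basins)), c(-1, 1))
})

test_that("mfpt on the raw coordinate equals mfpt on the natural one", {
  s <- simulate_doublewell(doublewell_config(4, 2, 1, n_steps = 2e6,
                                             dt_integrate = 1e-3,
                                             save_stride = 2, seed = 3))
  h <- histogram_profile(s, 32)
  cp <- cut_profile(s, levels = h$level, k = 1)
  dp <- diffusion_profile(h, cp)
  m_raw <- kramers_mfpt(h, -1, 1, diffusion = dp)
  nt <- natural_transform(s, hist = h, cut = cp)
  hn <- histogram_profile(nt$series, 32)
  m_nat <- kramers_mfpt(hn, apply_map(nt$map, -1), apply_map(nt$map, 1))
  expect_equal(m_nat, m_raw, tolerance = 0.1)
  # and both sit near the true Kramers value for this potential
  expect_equal(m_raw, 17.3, tolerance = 0.15)
})

test_that("kinetics report assembles a consistent JSON-serializable summary", {
  s <- simulate_doublewell(doublewell_config(4, 2, 1, n_steps = 2e6,
                                             dt_integrate = 1e-3,
                                             save_stride = 2, seed = 3))
  kin <- kinetics_report(s, n_bins = 32, k = 1)
  expect_gt(kin$mfpt_forward, 0)
  expect_equal(kin$n_events_est,
               kin$duration / (kin$mfpt_forward + kin$mfpt_backward))
  expect_gt(kin$barrier_height_kT, 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_kinetics(kin, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$n_events_est, kin$n_events_est, tolerance = 1e-9)
  g <- glance(kin)
  expect_equal(g$x_TS, kin$x_TS)
})
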