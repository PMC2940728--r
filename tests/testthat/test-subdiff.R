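test_that("a strictly increasing ramp is ballistic (alpha = 1)", {
  s <- scalar_series(as.numeric(1:2000))
  ap <- alpha_profile(s, levels = 1000.5, k1 = 1, k2 = 2)
  expect_equal(ap$alpha, 1)
  sc <- cut_scan(s, 1000.5, strides = c(1, 2, 4, 8))
  expect_equal(sc$Z_C, rep(0.5, 4))
})

test_that("Brownian motion gives alpha = 1/2 at the median level", {
  alphas <- vapply(1:20, function(seed) {
    s <- brownian_series(1e5, seed = seed)
    suppressWarnings(alpha_profile(s, levels = median(series_values(s)),
                                   k1 = 4, k2 = 8))$alpha
  }, 1.0)
  expect_lt(abs(mean(alphas) - 0.5), 0.05)
})

test_that("the estimator recovers the Hurst exponent of fBm", {
  s <- simulate_fbm(fbm_config(0.25, 2^16, seed = 2))
  a <- suppressWarnings(alpha_profile(s, levels = median(series_values(s)),
                                      k1 = 4, k2 = 8))$alpha
  expect_lt(abs(a - 0.25), 0.05)
})

test_that("alpha is exactly invariant under monotone reparametrization", {
  s <- brownian_series(5e4, seed = 6)
  v <- series_values(s)
  lv <- quantile(v, c(0.3, 0.5, 0.7), names = FALSE)
  a1 <- suppressWarnings(alpha_profile(s, levels = lv, k1 = 2, k2 = 4)$alpha)
  a2 <- suppressWarnings(
    alpha_profile(scalar_series(v^3), levels = lv^3, k1 = 2, k2 = 4)$alpha)
  expect_identical(a2, a1)
})

test_that("telegraph dynamics shows the ballistic plateau and its decay", {
  s <- telegraph_series(400, 1000, seed = 9)
  n_tr <- count_transitions(s, 0.25, 0.75)$n_switches
  sc <- cut_scan(s, 0.5, strides = c(1, 2, 4, 8, 16, 32))
  expect_true(all(abs(sc$Z_C - n_tr / 2) / (n_tr / 2) < 0.1))
  scL <- cut_scan(s, 0.5, strides = c(1, 4, 1024, 2048, 4096))
  expect_lt(tail(scL$Z_C, 1), 0.6 * n_tr / 2)
  expect_error(cut_scan(s, 5, strides = c(1, 2)), "outside")
  expect_error(cut_scan(s, 0.5, strides = c(4, 2)), "increasing")
})

test_that("two-line fit recovers known scan parameters within 5%", {
  k <- 2^(0:12)
  z_true <- ifelse(k < 500, 100 * (k / 500)^(0.4 - 1), 100)
  set.seed(2)
  sc <- fake_cut_scan(k, z_true * exp(rnorm(length(k), 0, 0.01)))
  fit <- fit_two_line(sc)
  expect_equal(fit$regime, "two_line")
  expect_equal(fit$alpha, 0.4, tolerance = 0.05)
  expect_equal(fit$Z_bal, 100, tolerance = 5)
  expect_equal(fit$t_bal, 500, tolerance = 25)
  expect_equal(fit$w, fit$t_bal^fit$alpha)
  # the fitted two-line model reproduces the scan
  expect_lt(max(abs(log(fit$fitted$Z_C_fit) - log(fit$fitted$Z_C))), 0.05)
})

test_that("degenerate scans are flagged, not forced", {
  flat <- fake_cut_scan(2^(0:6), rep(100, 7))
  f1 <- fit_two_line(flat)
  expect_equal(f1$regime, "plateau_only")
  expect_true(is.na(f1$alpha))

  sloped <- fake_cut_scan(2^(0:6), 100 * (2^(0:6))^(-0.5))
  f2 <- fit_two_line(sloped)
  expect_equal(f2$regime, "sloped_only")
  expect_equal(f2$alpha, 0.5, tolerance = 1e-6)
  expect_true(is.na(f2$t_bal))
})

test_that("closed-form exponent reproduces the worked barrier values", {
  # (F_ts, t_bal) pairs with Z_bal = 100 events, base interval 1
  res <- alpha_from_barrier(c(-9.72, -8.34, -7.13), 100,
                            c(1924, 487, 144), dt0 = 1)
  expect_lt(max(abs(res$alpha - c(0.32, 0.39, 0.49))), 0.01)
  expect_equal(alpha_from_barrier(-log(100), 100, 500)$alpha, 1)
  expect_warning(alpha_from_barrier(-2, 100, 500), "over-fitting")
  expect_error(alpha_from_barrier(-5, 100, t_bal = 0.5), "t_bal")
})

test_that("two-line fit and the closed form are mutually consistent", {
  k <- 2^(0:12)
  z <- ifelse(k < 800, 120 * (k / 800)^(0.35 - 1), 120)
  fit <- fit_two_line(fake_cut_scan(k, z))
  f_ts <- -log(fit$Z_bal * (fit$dt0 / fit$t_bal)^(fit$alpha - 1))
  back <- alpha_from_barrier(f_ts, fit$Z_bal, fit$t_bal, fit$dt0)
  expect_equal(back$alpha, fit$alpha, tolerance = 1e-6)
})

test_that("MSD from a window has diffusive slope 2D on Brownian input", {
  s <- brownian_series(1e6, D = 1, seed = 12)
  m <- msd_from_window(s, level = median(series_values(s)), half_width = 2,
                       max_lag = 200)
  sel <- m$lag <= 100
  expect_true(all(m$msd[sel] / m$lag[sel] > 1.8 &
                    m$msd[sel] / m$lag[sel] < 2.2))
})

test_that("MSD of a deterministic ramp is exactly ballistic", {
  s <- scalar_series(as.numeric(1:5000))
  m <- msd_from_window(s, level = 2500, half_width = 2500, max_lag = 100)
  expect_equal(m$msd, m$lag^2)
  expect_equal(attr(m, "gamma"), 2, tolerance = 1e-6)
})

test_that("fBm MSD exponent is 2H and the MAD exponent matches alpha", {
  s <- simulate_fbm(fbm_config(0.25, 2^17, seed = 4))
  m <- msd_from_window(s, level = median(series_values(s)), half_width = 5,
                       max_lag = 400)
  expect_lt(abs(attr(m, "gamma") - 0.5), 0.1)
  expect_lt(abs(attr(m, "gamma") - 2 * attr(m, "alpha")), 0.05)
  expect_error(msd_from_window(s, level = 1e6, half_width = 1), "no origins")
})

test_that("stride recommendation keys on the coordinate's value resolution", {
  expect_equal(recommend_strides(brownian_series(1e4, seed = 1), 0), c(1, 2))
  set.seed(3)
  w <- scalar_series(cumsum(sample(c(-1, 1), 2e4, TRUE)))
  ks <- recommend_strides(w, 0)
  expect_equal(ks[2], 2 * ks[1])
  o <- which(abs(series_values(w)) <= 0.5)
  o <- o[o + ks[1] <= 2e4]
  expect_gte(mean(abs(series_values(w)[o + ks[1]] - series_values(w)[o])),
             1.9)
})
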