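test_that("histogram counts, masking and cumulative mass behave as defined", {
  h <- histogram_profile(scalar_series(c(0.1, 0.1, 0.9)), bins = c(0, 0.5, 1))
  expect_equal(h$count, c(2, 1))
  z <- cumulative_coordinate(h)
  expect_equal(apply_map(z, 0.5), 2 / 3)
  expect_equal(apply_map(z, 0), 0)
  expect_equal(apply_map(z, 1), 1)
  expect_error(histogram_profile(scalar_series(1:10), bins = 2), ">= 3")

  hc <- histogram_profile(scalar_series(rep(5, 10)), bins = 7)
  expect_equal(sum(hc$count > 0), 1)
  expect_true(all(hc$masked[hc$count == 0]))
  expect_true(all(is.na(hc$F_H[hc$masked])))
})

test_that("uniform draws give a flat free-energy profile", {
  set.seed(14)
  h <- histogram_profile(scalar_series(runif(1e6)), bins = 20)
  expect_lt(max(abs(h$F_H - mean(h$F_H))), 0.05)
  expect_equal(sum(h$count), 1e6)
  expect_equal(tail(attr(h, "phi_edges"), 1), 1)
})

test_that("cut profile counts transitions with the half-count convention", {
  s <- scalar_series(c(0, 1, 0, 1, 0))
  cp <- cut_profile(s, levels = 0.5, k = 1, offset_mode = "single")
  expect_equal(cp$Z_C, 2)
  expect_equal(cp$F_C, -log(2))
  expect_warning(out <- cut_profile(s, levels = 1.5, k = 1), "outside")
  expect_equal(out$Z_C, 0)
  expect_true(out$masked)
  expect_error(cut_profile(s, levels = 0.5, k = 2), "too large")
})

test_that("brute-force oracle matches the kernel for arbitrary series", {
  set.seed(7)
  v <- cumsum(rnorm(500))
  levels <- sort(runif(37, min(v), max(v)))
  for (k in c(1, 3, 7)) {
    expect_identical(cut_profile(scalar_series(v), levels, k)$crossings,
                     brute_cut_counts(v, levels, k, TRUE))
    expect_identical(
      cut_profile(scalar_series(v), levels, k,
                  offset_mode = "single")$crossings,
      brute_cut_counts(v, levels, k, FALSE))
  }
})

test_that("Z_C is exactly invariant under strictly monotone maps", {
  set.seed(5)
  v <- cumsum(rnorm(2e4))
  levels <- quantile(v, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  base <- cut_profile(scalar_series(v), levels, k = 2)
  for (g in list(function(x) x^3, exp, function(x) 2 * x + 7)) {
    mapped <- cut_profile(scalar_series(g(v)), g(levels), k = 2)
    expect_identical(mapped$crossings, base$crossings)
  }
})

test_that("diffusive scaling: ln Z_C drops by ln(2)/2 per stride doubling", {
  drops <- vapply(1:20, function(seed) {
    v <- series_values(brownian_series(1e5, seed = seed))
    med <- median(v)
    z <- vapply(c(1, 2, 4), function(k)
      cut_profile(scalar_series(v), med, k = k)$Z_C, 1.0)
    mean(diff(log(z)))
  }, 1.0)
  expect_lt(abs(mean(drops) - (-0.5 * log(2))),
            3 * sd(drops) / sqrt(length(drops)))
})

test_that("diffusion profile implements the displacement formula and masks", {
  s <- brownian_series(2e4, seed = 3)
  h <- histogram_profile(s, 24)
  cp <- cut_profile(s, levels = h$level, k = 2)
  dp <- diffusion_profile(h, cp)
  ok <- !dp$masked
  expect_equal(dp$mad[ok], 2 * 2 * cp$Z_C[ok] / h$zh_len[ok])
  expect_equal(dp$D[ok], pi * dp$mad[ok]^2 / (4 * 2), tolerance = 1e-12)
  expect_true(all(is.na(dp$D[cp$Z_C == 0])))
  expect_error(diffusion_profile(h, cut_profile(s, levels = h$level + 0.5,
                                                k = 2)),
               "grids")
})

test_that("known-D free diffusion is recovered on well-sampled levels", {
  # reflect a D = 2 walk into [0, 40]: stationary uniform density, local
  # dynamics untouched away from the edges
  refl <- function(x, L) { m <- x %% (2 * L); ifelse(m > L, 2 * L - m, m) }
  set.seed(4)
  s <- scalar_series(refl(cumsum(rnorm(1e6, sd = sqrt(2 * 2))), 40))
  h <- histogram_profile(s, 30)
  cp <- cut_profile(s, levels = h$level, k = 4)
  dp <- diffusion_profile(h, cp)
  inner <- h$level > 4 & h$level < 36 & !dp$masked
  expect_gt(sum(inner), 10)
  expect_true(all(dp$D[inner] > 1.8 & dp$D[inner] < 2.2))
})

test_that("natural transform rescales constant-D coordinates linearly", {
  refl <- function(x, L) { m <- x %% (2 * L); ifelse(m > L, 2 * L - m, m) }
  set.seed(6)
  s4 <- scalar_series(refl(cumsum(rnorm(2e5, sd = sqrt(2 * 4))), 40))
  nt <- natural_transform(s4, n_bins = 24, k = 2)
  slope <- diff(unname(apply_map(nt$map, c(10, 30)))) / 20
  expect_equal(slope, 1 / sqrt(4), tolerance = 0.05)

  set.seed(6)
  s1 <- scalar_series(refl(cumsum(rnorm(2e5, sd = sqrt(2))), 40))
  nt1 <- natural_transform(s1, n_bins = 24, k = 2)
  expect_equal(diff(unname(apply_map(nt1$map, c(10, 30)))) / 20, 1,
               tolerance = 0.05)
})

test_that("cube distortion round-trips to unit diffusion where well sampled", {
  s <- simulate_doublewell(doublewell_config(4, 2, 1, n_steps = 2e6,
                                             dt_integrate = 1e-3,
                                             save_stride = 2, seed = 3))
  distorted <- scalar_series(series_values(s)^3, dt = series_dt(s))
  nt <- natural_transform(distorted, n_bins = 32, k = 1)
  pt <- profile_table(nt$series, n_bins = 32, k = 1)
  well <- pt$Z_H >= 0.05 * nrow(s) & !pt$masked_cut
  expect_gt(sum(well), 5)
  expect_true(all(abs(pt$D[well] - 1) < 0.15))
  # crossing counts at mapped levels are untouched by the transform
  lv <- quantile(series_values(distorted), c(0.3, 0.5, 0.7), names = FALSE)
  before <- cut_profile(distorted, lv, k = 1)$crossings
  after <- cut_profile(nt$series, apply_map(nt$map, lv), k = 1)$crossings
  expect_identical(after, before)
})

test_that("F_C against the cumulative coordinate is reparametrization-proof", {
  s <- simulate_doublewell(doublewell_config(4, 2, 1, n_steps = 4e5,
                                             dt_integrate = 1e-3,
                                             save_stride = 2, seed = 8))
  v <- series_values(s)
  g <- function(x) x^3
  lv <- quantile(v, seq(0.1, 0.9, by = 0.1), names = FALSE)
  fc1 <- cut_profile(s, lv, k = 1)$F_C
  z1 <- apply_map(cumulative_coordinate(histogram_profile(s, 40)), lv)
  s2 <- scalar_series(g(v), dt = series_dt(s))
  fc2 <- cut_profile(s2, g(lv), k = 1)$F_C
  z2 <- apply_map(cumulative_coordinate(histogram_profile(s2, 40)), g(lv))
  expect_identical(fc2, fc1)              # same crossings
  expect_equal(z2, z1, tolerance = 0.01)  # same invariant abscissa
})

test_that("profile table writes and rereads the joined TSV", {
  s <- brownian_series(5e3, seed = 10)
  tbl <- profile_table(s, n_bins = 12, k = 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(tbl, p)
  hdr <- readLines(p, n = 7)
  expect_true(any(grepl("stride = 1", hdr)))
  back <- utils::read.delim(p, comment.char = "#")
  expect_equal(nrow(back), nrow(tbl))
  expect_equal(back$Z_C, tbl$Z_C)
})
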