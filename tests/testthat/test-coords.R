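mk_traj <- function(...) {
  frames <- list(...)
  m <- nrow(frames[[1]])
  coords <- array(NA_real_, c(length(frames), m, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  atom_trajectory(coords)
}

test_that("pairwise distances are Euclidean and reject degenerate pairs", {
  tr <- mk_traj(rbind(c(0, 0, 0), c(3, 4, 0)),
                rbind(c(1, 1, 1), c(1, 1, 1)))
  d <- pairwise_distance(tr, c(0, 1))
  expect_equal(series_values(d), c(5, 0))
  expect_error(pairwise_distance(tr, c(1, 1)), "degenerate")
  expect_error(pairwise_distance(tr, c(0, 5)), "range")
})

test_that("contact coordinate follows the step convention with step(0) = 1", {
  tr <- mk_traj(rbind(c(0, 0, 0), c(3, 0, 0)),
                rbind(c(0, 0, 0), c(6, 0, 0)),
                rbind(c(0, 0, 0), c(5, 0, 0)))
  spec <- contact_spec(rbind(c(0, 1)), signs = 1, thresholds = 5)
  expect_equal(series_values(eval_contact_coordinate(tr, spec)), c(1, 0, 1))
  spec$signs <- -1
  expect_equal(series_values(eval_coordinate(tr, spec)), c(-1, 0, -1))
})

test_that("multi-pair contact sums count formed contacts", {
  # distances 3, 4.9, 5.1 against threshold 5 -> 2 formed (boundary closed)
  fr <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4.9, 0), c(0, 0, -5.1))
  tr <- mk_traj(fr, fr)
  spec <- contact_spec(rbind(c(0, 1), c(0, 2), c(0, 3)),
                       signs = c(1, 1, 1), thresholds = rep(5, 3))
  expect_equal(series_values(eval_coordinate(tr, spec)), c(2, 2))
})

test_that("distance coordinate is a weighted sum and flags degeneracy", {
  fr <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 6, 0))
  tr <- mk_traj(fr, fr)
  single <- distance_spec(rbind(c(0, 1)), weights = 1)
  expect_equal(series_values(eval_distance_coordinate(tr, single)),
               series_values(pairwise_distance(tr, c(0, 1))))
  avg <- distance_spec(rbind(c(0, 1), c(0, 2)), weights = c(0.5, 0.5))
  expect_equal(series_values(eval_coordinate(tr, avg)), c(5, 5))
  expect_error(distance_spec(rbind(c(0, 1)), weights = 0), "nonzero")
})

test_that("native contact construction honours cutoff, mode and separation", {
  native <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  spec <- native_contact_init(native, cutoff = 5)
  expect_equal(spec$pairs, rbind(c(0L, 1L), c(1L, 2L)), ignore_attr = TRUE)
  expect_true(all(spec$signs == 1))
  prop <- native_contact_init(native, cutoff = 5, mode = "proportional",
                              lambda = 1.2)
  expect_equal(prop$thresholds, c(4.8, 4.8))
  expect_error(native_contact_init(native, cutoff = 3), "no native contacts")
  far <- native_contact_init(native, cutoff = 9, min_seq_sep = 2)
  expect_equal(far$pairs, rbind(c(0L, 2L)), ignore_attr = TRUE)
})

test_that("both families are invariant to rigid motions", {
  two <- make_small_twostate(n_frames = 500, seed = 21)
  tr <- two$trajectory
  set.seed(8)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- c(5, -3, 2)
  moved <- tr
  for (f in seq_len(n_frames(tr)))
    moved$coords[f, , ] <- matrix(tr$coords[f, , ], ncol = 3) %*% rot +
      rep(shift, each = n_atoms(tr))
  q1 <- native_contact_init(toy_structures()$a, cutoff = 7)
  expect_equal(series_values(eval_coordinate(moved, q1)),
               series_values(eval_coordinate(tr, q1)))
  q2 <- distance_spec(rbind(c(0, 7), c(2, 5)), weights = c(1, -0.5))
  expect_equal(series_values(eval_coordinate(moved, q2)),
               series_values(eval_coordinate(tr, q2)), tolerance = 1e-10)
})

test_that("contact output is integer-valued and bounded by the pair count", {
  two <- make_small_twostate(n_frames = 2e3, seed = 22)
  spec <- scramble_signs(native_contact_init(toy_structures()$a, 7), seed = 5)
  v <- series_values(eval_coordinate(two$trajectory, spec))
  expect_true(all(v == round(v)))
  expect_true(all(abs(v) <= nrow(spec$pairs)))
})

test_that("incremental re-evaluation equals full re-evaluation", {
  two <- make_small_twostate(n_frames = 2e3, seed = 23)
  tr <- two$trajectory
  spec <- native_contact_init(toy_structures()$a, 7)
  v <- series_values(eval_coordinate(tr, spec))
  p <- 3                       # change one pair's parameters
  d <- series_values(pairwise_distance(tr, spec$pairs[p, ]))
  base <- v - spec$signs[p] * (d <= spec$thresholds[p])
  spec2 <- spec
  spec2$signs[p] <- -1
  spec2$thresholds[p] <- 6.2
  incr <- base + spec2$signs[p] * (d <= spec2$thresholds[p])
  expect_identical(incr, series_values(eval_coordinate(tr, spec2)))

  q2 <- distance_spec(rbind(c(0, 7), c(1, 6), c(2, 5)),
                      weights = c(0.5, -0.2, 0.8))
  v2 <- series_values(eval_coordinate(tr, q2))
  d2 <- series_values(pairwise_distance(tr, c(1, 6)))
  q2b <- q2; q2b$weights[2] <- 0.4
  expect_equal(v2 - (-0.2) * d2 + 0.4 * d2,
               series_values(eval_coordinate(tr, q2b)), tolerance = 1e-12)
})

test_that("coordinate specs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  spec <- contact_spec(rbind(c(0, 3), c(1, 5)), signs = c(1, -1),
                       thresholds = c(5.5, 7.25))
  write_coordinate_spec(spec, path)
  back <- read_coordinate_spec(path)
  expect_equal(back$pairs, spec$pairs, ignore_attr = TRUE)
  expect_equal(back$signs, spec$signs)
  expect_equal(back$thresholds, spec$thresholds)

  q2 <- distance_spec(rbind(c(0, 1)), weights = 0.75)
  write_coordinate_spec(q2, path)
  expect_equal(read_coordinate_spec(path)$weights, 0.75)
})
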