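#' Optimizer configuration
#'
#' Controls the stochastic coordinate ascent that constructs near-optimal
#' reaction coordinates: at each proposal a random pair is drawn, that
#' pair's parameters are scanned on a grid with everything else fixed, and
#' the best grid point is accepted iff it strictly increases the objective.
#'
#' @param objective `"mfpt"` (round-trip basin-averaged Kramers mfpt between
#'   the two deepest cut-FEP basins — orientation-invariant, so candidate
#'   coordinates that flip sign remain comparable) or `"min_crossings"`
#'   (maximize the transition-count proxy `n_A * dt / (2 Z_C(TS))`).
#' @param n_sweeps sweep budget; a sweep is `proposals_per_sweep` proposals.
#' @param proposals_per_sweep default: the number of candidate pairs.
#' @param grid_points threshold grid size per pair for the contacts family
#'   (placed between the `threshold_range` percentiles of that pair's
#'   observed distances).
#' @param threshold_range percentile bounds (0-100) for threshold scans.
#' @param weight_points weight grid size for the distances family (uniform
#'   on `[-weight_range, weight_range]`, always including 0).
#' @param weight_range symmetric weight bound (weights are renormalized to
#'   unit L2 norm after each acceptance, so only the relative scale matters).
#' @param n_bins mass-uniform profile bins used inside the objective (the
#'   barrier region holds only a few percent of the mass, so resolution
#'   there needs of order 100 bins; integer-valued coordinates use unit
#'   bins regardless).
#' @param stride cut-profile stride used inside the objective.
#' @param seed integer seed; the run is fully replayable from it.
#' @param stall_limit proposals without acceptance before stopping
#'   (default `2 x` the number of candidate pairs).
#' @param candidate_pairs optional pair matrix restricting proposals
#'   (contacts default: the pairs of the initial spec, i.e. native-only;
#'   distances default: all atom pairs).
#' @param holdout if `TRUE`, optimize on the first half of the trajectory
#'   and report the objective on the second half (over-fitting guard).
#' @return an `optimizer_config` list.
#' @export
optimizer_config <- function(objective = c("mfpt", "min_crossings"),
                             n_sweeps = 5, proposals_per_sweep = NULL,
                             grid_points = 12, threshold_range = c(5, 95),
                             weight_points = 21, weight_range = 1,
                             n_bins = 128, stride = 1, seed = NULL,
                             stall_limit = NULL, candidate_pairs = NULL,
                             holdout = FALSE) {
  objective <- match.arg(objective)
  if (n_sweeps < 1 || grid_points < 2 || weight_points < 3)
    abort("n_sweeps >= 1, grid_points >= 2, weight_points >= 3 required")
  if (any(threshold_range <= 0) || any(threshold_range >= 100) ||
      threshold_range[1] >= threshold_range[2])
    abort("threshold_range must be increasing percentiles inside (0, 100)")
  structure(list(objective = objective, n_sweeps = n_sweeps,
                 proposals_per_sweep = proposals_per_sweep,
                 grid_points = grid_points, threshold_range = threshold_range,
                 weight_points = weight_points, weight_range = weight_range,
                 n_bins = n_bins, stride = stride, seed = seed,
                 stall_limit = stall_limit, candidate_pairs = candidate_pairs,
                 holdout = holdout),
            class = "optimizer_config")
}

#' Objective functional: round-trip Kramers mfpt of a projected series
#'
#' The profile pipeline behind the optimizer: equal-population histogram
#' (unit-width integer bins for integer-valued coordinates), cut profile,
#' diffusion profile, transition-state location, and basin-averaged Kramers
#' mfpt in both directions.  The value maximized is `mfpt_fwd + mfpt_bwd`
#' (equivalently, minimal estimated event count).  Barrier-less profiles
#' fall back to the full-range one-way mfpt and are flagged.  Computing the
#' mfpt on the raw coordinate with its diffusion profile is equivalent to
#' computing it on the natural coordinate with `D = 1`.
#'
#' @param series a [scalar_series()] or numeric vector.
#' @param n_bins profile bins.
#' @param stride cut stride.
#' @param objective `"mfpt"` or `"min_crossings"`.
#' @param native_value optional coordinate value of the native reference
#'   structure; when given, the `"mfpt"` objective is the one-way
#'   basin-averaged mfpt into the basin containing that value (the target
#'   stays pinned to the native structure however the coordinate is
#'   reshaped); otherwise it is the orientation-invariant round trip.
#' @return a list: `value` (the maximized objective), `mfpt_forward`,
#'   `mfpt_backward`, `n_events_est`, `x_TS`, `F_TS`, `flagged`.
#' @export
objective_mfpt <- function(series, n_bins = 128, stride = 1,
                           objective = "mfpt", native_value = NULL) {
  v <- if (inherits(series, "scalar_series")) series_values(series) else series
  dt <- if (inherits(series, "scalar_series")) series_dt(series) else 1
  out <- obj_eval(v, dt, n_bins, stride, objective, native_value)
  if (is.null(out)) abort("objective not computable: degenerate coordinate")
  out
}

# Fast internal objective evaluation; returns NULL for degenerate candidates.
# native_value: the candidate coordinate's value on the native reference
# structure.  When given, the objective is the one-way basin-averaged mfpt
# into the basin containing that value ("mfpt to the native basin");
# identifying the target through the native structure keeps it
# invariant as candidate coordinates reshape and prevents the optimizer from
# chasing rarely-visited extreme levels.  Without it the objective is the
# orientation-invariant round trip.
obj_eval <- function(v, dt, n_bins, stride, objective, native_value = NULL,
                     min_support = 16) {
  if (diff(range(v)) == 0) return(NULL)
  n <- length(v)
  is_int <- all(v == round(v)) && diff(range(v)) <= 512
  if (is_int) {
    if (diff(range(v)) < 3) return(NULL)
    edges <- seq(min(v) - 0.5, max(v) + 0.5, by = 1)
    cuts <- seq(min(v), max(v) - 1)          # integer cut = upper bin edge
  } else {
    # quantile edges and mid-mass cut levels: both are equivariant under
    # strictly monotone reparametrization, making the objective invariant
    probs <- seq(0, 1, length.out = n_bins + 1)
    edges <- unique(quantile(v, probs, names = FALSE))
    if (length(edges) < 5) return(NULL)
    cuts <- unique(quantile(v, (head(probs, -1) + tail(probs, -1)) / 2,
                            names = FALSE))
    if (length(cuts) != length(edges) - 1) return(NULL)
  }
  nb <- length(edges) - 1
  idx <- findInterval(v, edges, left.open = TRUE)
  idx[idx == 0 & v <= edges[1]] <- 1L
  counts <- tabulate(idx, nbins = nb)
  phi_edges <- c(0, cumsum(counts) / n)
  phi_mid <- (head(phi_edges, -1) + tail(phi_edges, -1)) / 2
  if (is_int) {
    # integer coordinates: cuts sit on the boundaries between value bins;
    # each bin carries its upper boundary's count (top bin reuses the last)
    zc_raw <- cpp_cut_counts(v, as.numeric(cuts), as.integer(stride), TRUE) /
      (2 * stride)
    zc <- c(zc_raw, zc_raw[length(zc_raw)])
    cut_levels <- c(cuts, max(v))
  } else {
    zc <- cpp_cut_counts(v, as.numeric(cuts), as.integer(stride), TRUE) /
      (2 * stride)
    cut_levels <- cuts
  }
  # statistical-support floor: a crossing count below min_support raw
  # alternations cannot support the 1/Z_C^2 Kramers weight; such levels are
  # masked, terminal masked runs shrink the working range, and interior
  # masked gaps wider than 3 bins disqualify the candidate
  supported <- (zc * 2 * stride) >= min_support
  if (sum(supported) < 4) return(NULL)
  iL <- which(supported)[1]
  iR <- which(supported)[sum(supported)]
  keep <- iL:iR
  gaps <- rle(!supported[keep])
  if (any(gaps$values & gaps$lengths > 3)) return(NULL)
  zc <- zc[keep]; counts <- counts[keep]; phi_mid <- phi_mid[keep]
  cut_levels <- cut_levels[keep]
  phi_edges <- phi_edges[c(keep, iR + 1)]
  nb <- length(keep)
  supported <- supported[keep]
  fc <- ifelse(supported, -log(zc), NA_real_)
  cutp <- new_profile_tibble(
    tibble(level = cut_levels, crossings = zc * 2 * stride, Z_C = zc,
           F_C = fc, masked = !supported),
    "cut_profile")
  attr(cutp, "k") <- stride; attr(cutp, "dt") <- dt
  attr(cutp, "offset_mode") <- "average"
  ts <- tryCatch(locate_transition_state(cutp, native_value = native_value),
                 error = function(e) NULL)
  flagged <- is.null(ts)
  # invariant per-bin Kramers contribution: (N dt/(pi k)) * Phi_i c_i / Z_i^2
  contrib <- function(from_left) {
    Phi <- if (from_left) phi_mid else 1 - phi_mid
    f <- ifelse(supported, (n * dt / (pi * stride)) * Phi * counts / zc^2,
                NA_real_)
    ok <- which(!is.na(f))
    if (length(ok) < 2) return(NULL)
    approx(ok, f[ok], xout = seq_len(nb), rule = 2)$y
  }
  seg_sum <- function(f, i, j) {           # half-weight end bins
    if (i == j) return(0)
    r <- seq(min(i, j), max(i, j))
    sum(f[r]) - (f[r[1]] + f[r[length(r)]]) / 2
  }
  res <- tryCatch({
    if (flagged) {
      f <- contrib(TRUE)
      if (is.null(f)) NULL
      else {
        fwd <- seg_sum(f, 1, nb)
        list(value = fwd, mfpt_forward = fwd, mfpt_backward = NA_real_,
             n_events_est = NA_real_, x_TS = NA_real_, F_TS = NA_real_)
      }
    } else {
      i_ts <- which.min(abs(cutp$level - ts$x_TS))
      i_b <- vapply(ts$x_basins, function(xb)
        which.min(abs(cutp$level - xb)), 1L)
      if (objective == "min_crossings") {
        n_a <- phi_edges[i_ts + 1] * n
        list(value = n_a * stride * dt / (2 * ts$Z_C_TS),
             mfpt_forward = NA_real_, mfpt_backward = NA_real_,
             n_events_est = NA_real_, x_TS = ts$x_TS, F_TS = ts$F_TS)
      } else {
        fL <- contrib(TRUE); fR <- contrib(FALSE)
        if (is.null(fL) || is.null(fR)) NULL
        else {
          # equilibrium-weighted start over each source side of the TS
          wl <- counts[seq_len(i_ts)]; wl <- wl / sum(wl)
          wr <- counts[i_ts:nb]; wr <- wr / sum(wr)
          fwd <- sum(wl * vapply(seq_len(i_ts), function(j)
            seg_sum(fL, j, i_b[2]), 1.0))
          bwd <- sum(wr * vapply(i_ts:nb, function(j)
            seg_sum(fR, j, i_b[1]), 1.0))
          dur <- n * dt
          value <- if (is.null(native_value)) fwd + bwd
                   else if (native_value >= ts$x_TS) fwd else bwd
          list(value = value, mfpt_forward = fwd, mfpt_backward = bwd,
               n_events_est = dur / (fwd + bwd), x_TS = ts$x_TS,
               F_TS = ts$F_TS)
        }
      }
    }
  }, error = function(e) NULL)
  if (is.null(res)) return(NULL)
  res$flagged <- flagged
  res
}

# Equal-population bin edges (deduped quantiles); unit-width integer bins
# for integer-valued coordinates.  NULL if the candidate is too degenerate.
objective_edges <- function(v, n_bins) {
  rng <- range(v)
  if (all(v == round(v)) && diff(rng) <= 512) {
    if (diff(rng) < 3) return(NULL)
    return(seq(rng[1] - 0.5, rng[2] + 0.5, by = 1))
  }
  q <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                       names = FALSE))
  if (length(q) < 5) return(NULL)
  q
}

#' Stochastic coordinate-ascent optimization of a reaction coordinate
#'
#' Iteratively improves a [contact_spec()] or [distance_spec()] on a
#' trajectory: draw a random candidate pair; scan that pair's parameters on
#' a grid (contacts: sign in `{-1, +1}` x thresholds at percentile grid
#' points of the pair's observed distances; distances: weights on a uniform
#' grid including 0) with the coordinate re-evaluated incrementally; keep
#' the best grid point and accept iff its objective strictly exceeds the
#' incumbent.  Stops on the sweep budget or after `stall_limit` proposals
#' without acceptance.  Fully seeded and replayable.
#'
#' @param traj an [atom_trajectory()].
#' @param init the initial coordinate spec (must give a non-constant,
#'   non-degenerate series).
#' @param cfg an [optimizer_config()].
#' @param native optional native reference structure (`M x 3` matrix,
#'   single-frame trajectory, or file path); when supplied the mfpt
#'   objective is the one-way mfpt to the native basin (see
#'   [objective_mfpt()]), which is the recommended setting.
#' @return an `opt_trace`: `steps` (accepted steps: proposal index, pair,
#'   parameters, objective), `best_spec`, `objective_init`,
#'   `objective_final`, `log` (skipped degenerate candidates),
#'   `diagnostics`, and (if `holdout`) `holdout`.
#' @export
optimize_coordinate <- function(traj, init, cfg = optimizer_config(),
                                native = NULL) {
  stopifnot(inherits(traj, "atom_trajectory"),
            inherits(init, "coordinate_spec"),
            inherits(cfg, "optimizer_config"))
  family <- init$family
  natc <- if (is.null(native)) NULL else native_coords(native)
  n_all <- n_frames(traj)
  fit_n <- if (cfg$holdout) n_all %/% 2 else n_all
  dt <- traj$frame_spacing
  sub <- function(vals) vals[seq_len(fit_n)]
  cand_pairs <- cfg$candidate_pairs %||%
    if (family == "contacts") init$pairs else all_pairs(n_atoms(traj))
  cand_pairs <- as_pair_matrix(cand_pairs)
  n_cand <- nrow(cand_pairs)
  pps <- cfg$proposals_per_sweep %||% n_cand
  stall_limit <- cfg$stall_limit %||% (2L * n_cand)

  spec <- init
  values <- series_values(eval_coordinate(traj, spec))
  if (diff(range(values)) == 0)
    abort("initial coordinate is constant on the trajectory")
  nat_val <- if (is.null(natc)) NULL else eval_spec_single(spec, natc)
  cur <- obj_eval(sub(values), dt, cfg$n_bins, cfg$stride, cfg$objective,
                  nat_val)
  if (is.null(cur)) abort("objective not computable on the initial coordinate")
  obj0 <- cur$value

  steps <- list(); log <- list(); stall <- 0L; n_prop <- 0L
  with_seed(cfg$seed, {
    for (sweep in seq_len(cfg$n_sweeps)) {
      for (prop in seq_len(pps)) {
        n_prop <- n_prop + 1L
        pi <- sample.int(n_cand, 1)
        pair <- cand_pairs[pi, ]
        d <- pair_dist_values(traj$coords, pair[1] + 1L, pair[2] + 1L)
        d_nat <- if (is.null(natc)) NULL else
          sqrt(sum((natc[pair[1] + 1L, ] - natc[pair[2] + 1L, ])^2))
        scan <- if (family == "contacts")
          scan_contact_pair(spec, pair, d, values, sub, dt, cfg, d_nat, nat_val)
        else
          scan_distance_pair(spec, pair, d, values, sub, dt, cfg, d_nat, nat_val)
        if (!is.null(scan$skipped))
          log[[length(log) + 1L]] <-
            sprintf("proposal %d pair (%d,%d): %s", n_prop, pair[1], pair[2],
                    scan$skipped)
        if (!is.null(scan$best) &&
            (!scan$best$obj$flagged || cur$flagged) &&
            scan$best$obj$value > cur$value) {
          spec <- scan$best$spec
          values <- scan$best$values
          nat_val <- scan$best$nat_val
          cur <- scan$best$obj
          stall <- 0L
          steps[[length(steps) + 1L]] <- tibble(
            proposal = n_prop, sweep = sweep,
            pair_i = pair[1], pair_j = pair[2],
            param = scan$best$param, sign = scan$best$sign,
            objective = cur$value)
          if (family == "distances") {
            # unit-norm the weights (the coordinate's scale is meaningless and
            # the objective is invariant under the monotone rescale)
            nrm <- sqrt(sum(spec$weights^2))
            spec$weights <- spec$weights / nrm
            values <- values / nrm
            if (!is.null(nat_val)) nat_val <- nat_val / nrm
          }
        } else stall <- stall + 1L
        if (stall >= stall_limit) break
      }
      if (stall >= stall_limit) break
    }
  })
  steps <- if (length(steps)) dplyr::bind_rows(steps) else
    tibble(proposal = integer(), sweep = integer(), pair_i = integer(),
           pair_j = integer(), param = numeric(), sign = numeric(),
           objective = numeric())
  out <- structure(list(steps = steps, best_spec = spec,
                        objective_init = obj0, objective_final = cur$value,
                        final_eval = cur, n_proposals = n_prop,
                        log = unlist(log) %||% character(),
                        cfg = cfg, family = family),
                   class = "opt_trace")
  if (cfg$holdout) {
    hv <- values[(fit_n + 1L):n_all]
    ho <- obj_eval(hv, dt, cfg$n_bins, cfg$stride, cfg$objective)
    out$holdout <- list(objective = if (is.null(ho)) NA_real_ else ho$value,
                        n_frames = length(hv))
  }
  out
}

all_pairs <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  cbind(idx[, 1] - 1L, idx[, 2] - 1L)
}

scan_contact_pair <- function(spec, pair, d, values, sub, dt, cfg,
                              d_nat = NULL, nat_val = NULL) {
  row <- pair_row(spec$pairs, pair)
  base <- values
  base_nat <- nat_val
  if (!is.na(row)) {
    base <- base - spec$signs[row] * (d <= spec$thresholds[row])
    if (!is.null(nat_val))
      base_nat <- base_nat - spec$signs[row] * (d_nat <= spec$thresholds[row])
  }
  qs <- quantile(d, probs = seq(cfg$threshold_range[1], cfg$threshold_range[2],
                                length.out = cfg$grid_points) / 100,
                 names = FALSE)
  qs <- unique(qs[qs > 0])
  if (length(qs) == 0) return(list(skipped = "no usable thresholds"))
  best <- NULL; skipped <- NULL
  for (s in c(-1, 1)) for (r0 in qs) {
    cand <- base + s * (d <= r0)
    cand_nat <- if (is.null(nat_val)) NULL else base_nat + s * (d_nat <= r0)
    obj <- obj_eval(sub(cand), dt, cfg$n_bins, cfg$stride, cfg$objective,
                    cand_nat)
    if (is.null(obj)) { skipped <- "degenerate candidate(s) skipped"; next }
    if (cand_better(obj, best)) {
      new_spec <- spec
      if (is.na(row)) {
        new_spec$pairs <- rbind(new_spec$pairs, pair)
        new_spec$signs <- c(new_spec$signs, s)
        new_spec$thresholds <- c(new_spec$thresholds, r0)
      } else {
        new_spec$signs[row] <- s
        new_spec$thresholds[row] <- r0
      }
      best <- list(spec = new_spec, values = cand, obj = obj,
                   param = r0, sign = s, nat_val = cand_nat)
    }
  }
  list(best = best, skipped = skipped)
}

scan_distance_pair <- function(spec, pair, d, values, sub, dt, cfg,
                               d_nat = NULL, nat_val = NULL) {
  row <- pair_row(spec$pairs, pair)
  w_old <- if (is.na(row)) 0 else spec$weights[row]
  base <- values - w_old * d
  base_nat <- if (is.null(nat_val)) NULL else nat_val - w_old * d_nat
  grid <- unique(c(seq(-cfg$weight_range, cfg$weight_range,
                       length.out = cfg$weight_points), 0))
  best <- NULL; skipped <- NULL
  for (w in grid) {
    cand <- base + w * d
    cand_nat <- if (is.null(nat_val)) NULL else base_nat + w * d_nat
    obj <- obj_eval(sub(cand), dt, cfg$n_bins, cfg$stride, cfg$objective,
                    cand_nat)
    if (is.null(obj)) { skipped <- "degenerate candidate(s) skipped"; next }
    if (cand_better(obj, best)) {
      new_spec <- spec
      if (is.na(row)) {
        new_spec$pairs <- rbind(new_spec$pairs, pair)
        new_spec$weights <- c(new_spec$weights, w)
      } else new_spec$weights[row] <- w
      if (all(new_spec$weights == 0)) next
      best <- list(spec = new_spec, values = cand, obj = obj,
                   param = w, sign = NA_real_, nat_val = cand_nat)
    }
  }
  list(best = best, skipped = skipped)
}

# candidate ranking: a barriered (unflagged) profile always beats a
# barrier-less (flagged) one; within the same class, higher objective wins
cand_better <- function(obj, best) {
  if (is.null(best)) return(TRUE)
  if (obj$flagged != best$obj$flagged) return(!obj$flagged)
  obj$value > best$obj$value
}

pair_row <- function(pairs, pair) {
  hit <- which(pairs[, 1] == pair[1] & pairs[, 2] == pair[2])
  if (length(hit)) hit[1] else NA_integer_
}

#' @export
print.opt_trace <- function(x, ...) {
  cat(sprintf(paste0("<opt_trace (%s): %d proposals, %d accepted, ",
                     "objective %.4g -> %.4g>\n"),
              x$family, x$n_proposals, nrow(x$steps), x$objective_init,
              x$objective_final))
  invisible(x)
}

#' Over-fitting diagnostics for an optimized coordinate
#'
#' Exponents above 1/2 (apparent superdiffusion) are the signature of
#' over-fitting the trajectory by the coordinate.  This computes the
#' anomalous-exponent profile of the projected series with bootstrap
#' standard errors, flags levels where `alpha > 0.5 + 2 SE`, and reports
#' the exponent at the transition state, the barrier height, and (when the
#' true count is supplied) estimated vs. true event counts.
#'
#' @param trace an `opt_trace` (may be `NULL` for a bare-series check).
#' @param series the projected series of the trace's best coordinate (or any
#'   series to diagnose).
#' @param k1,k2 strides for the exponent estimate.
#' @param n_boot bootstrap replicates for standard errors.
#' @param true_events optional ground-truth transition count.
#' @return an `overfit_report`: `flags` tibble (level, alpha, se),
#'   `alpha_ts`, `se_ts`, `barrier_height_kT`, `n_events_est`,
#'   `n_events_true`.
#' @export
diagnose_overfit <- function(trace, series = NULL, k1 = 4, k2 = 8,
                             n_boot = 20, true_events = NULL) {
  if (is.null(series))
    return(structure(list(flags = tibble(level = numeric(), alpha = numeric(),
                                         se = numeric()),
                          alpha_ts = NA_real_, se_ts = NA_real_,
                          barrier_height_kT = NA_real_,
                          n_events_est = NA_real_,
                          n_events_true = true_events %||% NA_real_),
                     class = "overfit_report"))
  series <- as_scalar_series(series)
  ap <- alpha_profile(series, k1 = k1, k2 = k2, n_boot = n_boot)
  flags <- dplyr::filter(tibble::as_tibble(ap),
                         !.data$masked & is.finite(.data$se) &
                           .data$alpha > 0.5 + 2 * .data$se)
  kin <- tryCatch(kinetics_report(series), error = function(e) NULL)
  a_ts <- se_ts <- NA_real_
  if (!is.null(kin)) {
    i <- which.min(abs(ap$level - kin$x_TS))
    a_ts <- ap$alpha[i]; se_ts <- ap$se[i]
  }
  structure(list(flags = flags[, c("level", "alpha", "se")],
                 alpha_ts = a_ts, se_ts = se_ts,
                 barrier_height_kT = if (is.null(kin)) NA_real_
                                     else kin$barrier_height_kT,
                 n_events_est = if (is.null(kin)) NA_real_
                                else kin$n_events_est,
                 n_events_true = true_events %||% NA_real_),
            class = "overfit_report")
}

#' @export
print.overfit_report <- function(x, ...) {
  cat(sprintf(paste0("<overfit_report: %d flagged level(s); alpha(TS) = %.3f ",
                     "+- %.3f; barrier %.2f kT>\n"),
              nrow(x$flags), x$alpha_ts, x$se_ts, x$barrier_height_kT))
  invisible(x)
}

#' Write / read an optimization trace as JSON
#'
#' The trace contains every accepted step and the final spec, enough to
#' replay the run (`cfg` records the seed).
#'
#' @param trace an `opt_trace`.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
write_opt_trace <- function(trace, path) {
  stopifnot(inherits(trace, "opt_trace"))
  spec <- trace$best_spec
  spec_json <- list(family = spec$family,
                    pairs = unname(apply(spec$pairs, 1, as.list)))
  if (spec$family == "contacts") {
    spec_json$signs <- spec$signs; spec_json$thresholds <- spec$thresholds
  } else spec_json$weights <- spec$weights
  x <- list(steps = trace$steps, best_spec = spec_json,
            objective_init = trace$objective_init,
            objective_final = trace$objective_final,
            n_proposals = trace$n_proposals, log = trace$log,
            family = trace$family,
            seed = trace$cfg$seed %||% NA)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
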