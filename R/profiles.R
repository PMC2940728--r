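#' Level grid for profile evaluation
#'
#' Default discretization of a reaction coordinate.  For continuous series:
#' midpoints of `n` equal-width bins over the data range (ties between frames
#' and levels are then measure-zero).  For integer-valued series (contact
#' coordinates): half-integer levels between the observed min and max, so no
#' frame can ever sit exactly on a level.
#'
#' @param series a [scalar_series()] (or numeric vector).
#' @param n target number of levels for continuous data.
#' @return strictly increasing numeric vector of levels (length >= 3 for
#'   non-degenerate input).
#' @export
level_grid <- function(series, n = 32) {
  v <- if (inherits(series, "scalar_series")) series_values(series) else series
  rng <- range(v)
  if (all(v == round(v)) && diff(rng) >= 2 && diff(rng) <= 512)
    return(seq(rng[1] + 0.5, rng[2] - 0.5, by = 1))
  if (diff(rng) == 0) abort("cannot build a level grid on a constant series")
  edges <- seq(rng[1], rng[2], length.out = n + 1)
  (edges[-1] + edges[-(n + 1)]) / 2
}

#' Histogram partition function and conventional free-energy profile
#'
#' Bins the series and reports, per bin: count `Z_H`, density
#' `count / (n_frames * width)`, frames-per-unit-length `count / width`,
#' conventional free energy `F_H = -ln Z_H` (kT = 1; empty bins are masked,
#' never infinite), and the cumulative mass `Phi` (fraction of frames at or
#' left of the bin's right edge; `Phi` runs from 0 to 1 and houses the basin
#' partition function).
#'
#' @param series a [scalar_series()].
#' @param bins a single bin count (>= 3) or a numeric vector of edges.
#' @return a `hist_profile` tibble with columns `level` (bin midpoint),
#'   `count`, `width`, `density`, `zh_len`, `F_H`, `phi`, `masked`;
#'   attributes `edges`, `phi_edges`, `n_frames`, `dt`.
#' @export
histogram_profile <- function(series, bins = 50) {
  series <- as_scalar_series(series)
  v <- series_values(series)
  if (length(bins) == 1) {
    if (bins < 3) abort("n_bins must be >= 3")
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
  } else {
    edges <- sort(as.numeric(bins))
    if (length(edges) < 4 - 1) abort("need at least 3 edges (2 bins)")
    if (any(diff(edges) <= 0)) abort("bin edges must be strictly increasing")
  }
  nb <- length(edges) - 1
  # frames exactly at an edge go left; values at/below the first edge go to bin 1
  idx <- findInterval(v, edges, left.open = TRUE)
  idx[idx == 0 & v <= edges[1]] <- 1L
  inside <- idx >= 1 & idx <= nb
  counts <- tabulate(idx[inside], nbins = nb)
  n_used <- sum(inside)
  width <- diff(edges)
  masked <- counts == 0
  out <- new_profile_tibble(
    tibble(level = (edges[-1] + edges[-(nb + 1)]) / 2,
           count = counts, width = width,
           density = counts / (n_used * width),
           zh_len = counts / width,
           F_H = ifelse(masked, NA_real_, -log(counts)),
           phi = cumsum(counts) / n_used,
           masked = masked),
    "hist_profile")
  attr(out, "edges") <- edges
  attr(out, "phi_edges") <- c(0, cumsum(counts) / n_used)
  attr(out, "n_frames") <- n_used
  attr(out, "dt") <- series_dt(series)
  out
}

new_profile_tibble <- function(df, cls) {
  class(df) <- c(cls, class(df))
  df
}

#' Exact Boltzmann profile from a potential
#'
#' Builds a `hist_profile` whose bin contents follow the Boltzmann density
#' `exp(-U(x))` (kT = 1) exactly, instead of being estimated from a sampled
#' series — the noiseless reference for quadrature checks and for Kramers
#' mfpt on a known potential.
#'
#' @param potential function of position returning energy in kT.
#' @param range `c(lo, hi)` support.
#' @param n_bins number of bins.
#' @param n_frames nominal frame count the bin "counts" are scaled to.
#' @return a `hist_profile` (fractional counts).
#' @export
boltzmann_profile <- function(potential, range, n_bins = 200,
                              n_frames = 1e6) {
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  width <- diff(edges)
  w <- exp(-potential(mids)) * width
  p <- w / sum(w)
  counts <- p * n_frames
  out <- new_profile_tibble(
    tibble(level = mids, count = counts, width = width,
           density = p / width, zh_len = counts / width,
           F_H = -log(counts), phi = cumsum(counts) / n_frames,
           masked = counts == 0),
    "hist_profile")
  attr(out, "edges") <- edges
  attr(out, "phi_edges") <- c(0, cumsum(p))
  attr(out, "n_frames") <- n_frames
  attr(out, "dt") <- 1
  out
}

#' Cut-based partition function and free-energy profile
#'
#' `Z_C` at level `x` is half the number of sign alternations of
#' `(value - x)` between frames sampled `k` apart, so that its ballistic
#' plateau at the transition state counts folding events.  A frame exactly at
#' a level is assigned to the left side.  With `offset_mode = "average"`
#' (default) all `k` phase offsets are used and the count carries a `1/k`
#' factor (per-phase normalization, all data used); `"single"` uses phase 0
#' only without the factor.  `F_C = -ln Z_C`, masked where `Z_C = 0`.
#'
#' `Z_C` is exactly invariant under strictly monotone reparametrization of
#' the series (crossing counts only compare orderings).
#'
#' @param series a [scalar_series()].
#' @param levels level grid (strictly increasing; default [level_grid()]).
#' @param k sampling stride; the effective sampling interval is `k * dt`.
#' @param offset_mode `"average"` or `"single"`.
#' @return a `cut_profile` tibble with columns `level`, `crossings` (raw
#'   alternation count), `Z_C`, `F_C`, `masked`; attributes `k`, `dt`,
#'   `offset_mode`, `n_pairs_used`, `n_frames`.
#' @export
cut_profile <- function(series, levels = NULL, k = 1,
                        offset_mode = c("average", "single")) {
  series <- as_scalar_series(series)
  offset_mode <- match.arg(offset_mode)
  v <- series_values(series)
  n <- length(v)
  k <- as.integer(k)
  if (k < 1) abort("stride k must be >= 1")
  if (k >= n / 4) abort(sprintf("stride k = %d too large for %d frames", k, n))
  levels <- levels %||% level_grid(series)
  if (any(diff(levels) <= 0)) abort("levels must be strictly increasing")
  if (all(levels < min(v)) || all(levels > max(v)) ||
      !any(levels >= min(v) & levels <= max(v)))
    warn("level grid lies outside the data range; profile is all zeros")
  raw <- cpp_cut_counts(v, as.numeric(levels), k, offset_mode == "average")
  zc <- if (offset_mode == "average") raw / (2 * k) else raw / 2
  out <- new_profile_tibble(
    tibble(level = as.numeric(levels), crossings = raw, Z_C = zc,
           F_C = ifelse(zc > 0, -log(zc), NA_real_), masked = zc == 0),
    "cut_profile")
  attr(out, "k") <- k
  attr(out, "dt") <- series_dt(series)
  attr(out, "offset_mode") <- offset_mode
  attr(out, "n_pairs_used") <-
    if (offset_mode == "average") n - k else (n - 1) %/% k
  attr(out, "n_frames") <- n
  out
}

#' Coordinate-dependent diffusion coefficient from paired profiles
#'
#' Combines a histogram and a cut profile of the same series on the same
#' level grid.  The mean absolute displacement over the sampling interval
#' `dt_sample = k * dt` is `MAD(x) = 2 * Z_C(x) / Zh_k(x)` with `Zh_k` the
#' frames-per-unit-length of the series sampled at that interval
#' (`zh_len / k` from the full-frame histogram), and the diffusion
#' coefficient follows from the half-Gaussian displacement law
#' `MAD = sqrt(4 D dt_sample / pi)`:
#' `D(x) = pi * MAD(x)^2 / (4 dt_sample)`.
#'
#' @param hist a [histogram_profile()] whose levels are the bin midpoints.
#' @param cut a [cut_profile()] of the same series at those midpoints.
#' @return a `diffusion_profile` tibble with columns `level`, `mad`, `D`,
#'   `masked`; attribute `dt_sample`.
#' @export
diffusion_profile <- function(hist, cut) {
  stopifnot(inherits(hist, "hist_profile"), inherits(cut, "cut_profile"))
  if (nrow(hist) != nrow(cut) ||
      max(abs(hist$level - cut$level)) > 1e-9 * max(1, diff(range(hist$level))))
    abort("histogram and cut profiles are on different level grids")
  k <- attr(cut, "k")
  dt_sample <- k * attr(cut, "dt")
  masked <- hist$masked | cut$masked
  mad <- ifelse(masked, NA_real_, 2 * k * cut$Z_C / hist$zh_len)
  out <- new_profile_tibble(
    tibble(level = hist$level, mad = mad,
           D = ifelse(masked, NA_real_, pi * mad^2 / (4 * dt_sample)),
           masked = masked),
    "diffusion_profile")
  attr(out, "dt_sample") <- dt_sample
  out
}

#' Transform a coordinate to its natural coordinate
#'
#' Integrates `y(x) = int dx' / sqrt(D(x'))` (trapezoid over level midpoints)
#' so that on the mapped coordinate the diffusion coefficient is 1 and
#' diffusive dynamics is fully specified by the free-energy profile.  Masked
#' interior levels are bridged by linear interpolation of `1/sqrt(D)`;
#' masked terminal levels are dropped and the map is continued linearly with
#' the edge slope so every frame can be mapped.  Crossing counts at mapped
#' levels are identical to the originals (reparametrization invariance).
#'
#' @param series a [scalar_series()].
#' @param n_bins bins used when `hist` / `cut` are not supplied.
#' @param k stride used when `cut` is not supplied.
#' @param hist optional precomputed [histogram_profile()] (bin midpoints as
#'   levels).
#' @param cut optional precomputed [cut_profile()] on those midpoints.
#' @return `list(map = natural_map, series = scalar_series)`.
#' @export
natural_transform <- function(series, n_bins = 32, k = 1, hist = NULL,
                              cut = NULL) {
  series <- as_scalar_series(series)
  if (is.null(hist)) hist <- histogram_profile(series, n_bins)
  if (is.null(cut)) cut <- cut_profile(series, levels = hist$level, k = k)
  dp <- diffusion_profile(hist, cut)
  g <- 1 / sqrt(dp$D)                      # dy/dx
  ok <- !dp$masked & is.finite(g)
  if (sum(ok) < 2) abort("diffusion profile not computable on enough levels")
  x <- dp$level
  keep <- seq(min(which(ok)), max(which(ok)))   # drop masked terminal levels
  xk <- x[keep]; gk <- g[keep]
  if (anyNA(gk))                                # bridge masked interior levels
    gk <- approx(xk[!is.na(gk)], gk[!is.na(gk)], xout = xk)$y
  y <- c(0, cumsum(diff(xk) * (head(gk, -1) + tail(gk, -1)) / 2))
  v <- series_values(series)
  # continue linearly with the edge slope beyond the supported range
  x_ext <- c(min(v, xk[1]) - 1e-9, xk, max(v, xk[length(xk)]) + 1e-9)
  y_ext <- c(y[1] - gk[1] * (xk[1] - x_ext[1]), y,
             y[length(y)] + gk[length(gk)] * (x_ext[length(x_ext)] - xk[length(xk)]))
  if (any(diff(y_ext) <= 0))
    abort("internal consistency: natural map is not strictly increasing")
  map <- new_coordinate_map(x_ext, y_ext, "natural_map")
  list(map = map,
       series = scalar_series(apply_map(map, v), dt = series_dt(series),
                              provenance = c(attr(series, "provenance"),
                                             list(transform = "natural"))))
}

new_coordinate_map <- function(x, y, cls) {
  # flat stretches (empty bins) make the inverse one-to-many; keep the first
  # preimage of each image value
  u <- !duplicated(y)
  structure(list(table = tibble(x = x, y = y),
                 forward = approxfun(x, y, rule = 2),
                 inverse = approxfun(y[u], x[u], rule = 2)),
            class = c(cls, "coordinate_map"))
}

#' Apply or invert a coordinate map
#'
#' @param map a `natural_map` or `cumulative_map`.
#' @param x positions on the source (or image, for `invert_map`) coordinate.
#' @return mapped positions.
#' @export
apply_map <- function(map, x) {
  stopifnot(inherits(map, "coordinate_map"))
  map$forward(x)
}

#' @rdname apply_map
#' @export
invert_map <- function(map, x) {
  stopifnot(inherits(map, "coordinate_map"))
  map$inverse(x)
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat(sprintf("<%s: %d knots on [%.4g, %.4g]>\n", class(x)[1],
              nrow(x$table), min(x$table$x), max(x$table$x)))
  invisible(x)
}

#' Invariant cumulative coordinate
#'
#' The monotone map `z(x) = Phi(x)`: the fraction of sampled configurations
#' with coordinate value at or left of `x` (the relative partition function
#' of the segment up to `x`).  Profiles plotted against `z` are invariant
#' under monotone reparametrization of the underlying coordinate, so
#' different reaction coordinates can be compared on a common abscissa.
#'
#' @param hist a [histogram_profile()].
#' @return a `cumulative_map` (see [apply_map()]), linear within bins.
#' @export
cumulative_coordinate <- function(hist) {
  stopifnot(inherits(hist, "hist_profile"))
  new_coordinate_map(attr(hist, "edges"), attr(hist, "phi_edges"),
                     "cumulative_map")
}

#' Combined profile table and TSV export
#'
#' Runs histogram, cut, diffusion, natural-coordinate, and cumulative
#' computations on one series and joins them on the level grid, as written
#' by the pipeline: columns `level, Z_H, F_H, Z_C, F_C, D, y, z, masked`.
#'
#' @param series a [scalar_series()].
#' @param n_bins number of histogram bins.
#' @param k cut stride.
#' @param offset_mode passed to [cut_profile()].
#' @return a tibble with attributes recording stride, bins, tie rule, and
#'   offset mode.
#' @export
profile_table <- function(series, n_bins = 32, k = 1,
                          offset_mode = "average") {
  series <- as_scalar_series(series)
  hist <- histogram_profile(series, n_bins)
  cut <- cut_profile(series, levels = hist$level, k = k,
                     offset_mode = offset_mode)
  dp <- diffusion_profile(hist, cut)
  nat <- tryCatch(natural_transform(series, hist = hist, cut = cut),
                  error = function(e) NULL)
  zmap <- cumulative_coordinate(hist)
  out <- tibble(level = hist$level, Z_H = hist$count, F_H = hist$F_H,
                Z_C = cut$Z_C, F_C = cut$F_C, D = dp$D,
                y = if (is.null(nat)) NA_real_ else apply_map(nat$map, hist$level),
                z = apply_map(zmap, hist$level),
                masked_hist = hist$masked, masked_cut = cut$masked)
  attr(out, "k") <- k
  attr(out, "n_bins") <- n_bins
  attr(out, "n_frames") <- attr(hist, "n_frames")
  attr(out, "offset_mode") <- offset_mode
  attr(out, "dt") <- series_dt(series)
  out
}

#' @rdname profile_table
#' @param tbl a table from `profile_table()`.
#' @param path output TSV path.
#' @export
write_profile_table <- function(tbl, path) {
  hdr <- c("# difftrace profile table",
           sprintf("# stride = %d", attr(tbl, "k")),
           sprintf("# n_bins = %d", attr(tbl, "n_bins")),
           sprintf("# n_frames = %d", attr(tbl, "n_frames")),
           sprintf("# offset_mode = %s", attr(tbl, "offset_mode")),
           sprintf("# dt = %.17g", attr(tbl, "dt")),
           "# tie_rule = frames at a level count left")
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE))
  invisible(path)
}
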