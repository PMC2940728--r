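#' Parametric reaction-coordinate families
#'
#' Two families of scalar coordinates over an atom trajectory:
#'
#' * `contact_spec()` (the contacts family) generalizes the
#'   number-of-native-contacts coordinate:
#'   `R(t) = sum_ij s_ij * step(r0_ij - d_ij(t))` with per-pair sign
#'   `s_ij` in `{-1, +1}` and distance threshold `r0_ij`; `step(0) = 1`
#'   (a pair exactly at its threshold counts as formed — fixed convention,
#'   measure-zero for continuous data).
#' * `distance_spec()` (the distance-combination family) is a linear
#'   combination of interatom distances `R(t) = sum_ij c_ij * d_ij(t)`.
#'
#' Atom indices are 0-based everywhere (as in the JSON serialization), with
#' `i < j` per pair.
#'
#' @param pairs integer matrix (or list) of atom index pairs, 0-based.
#' @param signs per-pair signs, each -1 or +1 (contacts).
#' @param thresholds per-pair distance thresholds r0 in Angstrom (contacts).
#' @param native_distances optional native distances d^nat per pair.
#' @param lambda_scale optional lambda with `thresholds = lambda * d^nat`.
#' @param weights per-pair coefficients c_ij (distances family).
#' @return a `contact_spec` / `distance_spec` (both inherit
#'   `coordinate_spec`).
#' @export
contact_spec <- function(pairs, signs, thresholds, native_distances = NULL,
                         lambda_scale = NULL) {
  pairs <- as_pair_matrix(pairs)
  np <- nrow(pairs)
  if (np == 0) abort("contact_spec needs at least one pair")
  signs <- as.numeric(signs); thresholds <- as.numeric(thresholds)
  if (length(signs) != np || length(thresholds) != np)
    abort("signs and thresholds must have one entry per pair")
  if (!all(signs %in% c(-1, 1))) abort("signs must be -1 or +1")
  if (any(thresholds <= 0)) abort("thresholds must be > 0")
  if (!is.null(lambda_scale)) {
    if (is.null(native_distances))
      abort("lambda_scale requires native_distances")
    if (!isTRUE(all.equal(thresholds, lambda_scale * native_distances)))
      abort("thresholds must equal lambda_scale * native_distances")
  }
  structure(list(family = "contacts", pairs = pairs, signs = signs,
                 thresholds = thresholds,
                 native_distances = native_distances,
                 lambda_scale = lambda_scale),
            class = c("contact_spec", "coordinate_spec"))
}

#' @rdname contact_spec
#' @export
distance_spec <- function(pairs, weights) {
  pairs <- as_pair_matrix(pairs)
  np <- nrow(pairs)
  if (np == 0) abort("distance_spec needs at least one pair")
  weights <- as.numeric(weights)
  if (length(weights) != np) abort("weights must have one entry per pair")
  if (all(weights == 0)) abort("at least one weight must be nonzero")
  structure(list(family = "distances", pairs = pairs, weights = weights),
            class = c("distance_spec", "coordinate_spec"))
}

as_pair_matrix <- function(pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (anyNA(pairs) || any(pairs < 0)) abort("pairs must be non-negative 0-based indices")
  if (any(pairs[, 1] >= pairs[, 2]))
    abort("each pair must satisfy i < j (0-based)")
  if (anyDuplicated(paste(pairs[, 1], pairs[, 2])))
    abort("pairs must be unique")
  pairs
}

#' Per-frame distance between two atoms
#'
#' @param traj an [atom_trajectory()].
#' @param pair length-2 vector of 0-based atom indices, `i != j`.
#' @return a [scalar_series()] of Euclidean distances (Angstrom).
#' @export
pairwise_distance <- function(traj, pair) {
  stopifnot(inherits(traj, "atom_trajectory"))
  pair <- as.integer(pair)
  if (length(pair) != 2) abort("`pair` must have length 2")
  if (pair[1] == pair[2]) abort("degenerate pair: i must differ from j")
  m <- n_atoms(traj)
  if (any(pair < 0 | pair >= m))
    abort(sprintf("atom index out of range [0, %d)", m))
  scalar_series(pair_dist_values(traj$coords, pair[1] + 1L, pair[2] + 1L),
                dt = traj$frame_spacing,
                provenance = list(coordinate = sprintf("d(%d,%d)", pair[1], pair[2])))
}

# 1-based internal distance kernel
pair_dist_values <- function(coords, i, j) {
  dx <- coords[, i, 1] - coords[, j, 1]
  dy <- coords[, i, 2] - coords[, j, 2]
  dz <- coords[, i, 3] - coords[, j, 3]
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Evaluate a coordinate family on a trajectory
#'
#' `eval_coordinate()` dispatches on the spec family; the contacts family
#' yields an integer-valued series bounded by the number of pairs.
#'
#' @param traj an [atom_trajectory()].
#' @param spec a [contact_spec()] or [distance_spec()].
#' @return a [scalar_series()].
#' @export
eval_coordinate <- function(traj, spec) UseMethod("eval_coordinate", spec)

#' @rdname eval_coordinate
#' @export
eval_coordinate.contact_spec <- function(traj, spec) {
  check_spec_indices(traj, spec)
  vals <- numeric(n_frames(traj))
  for (p in seq_len(nrow(spec$pairs))) {
    d <- pair_dist_values(traj$coords, spec$pairs[p, 1] + 1L,
                          spec$pairs[p, 2] + 1L)
    vals <- vals + spec$signs[p] * (d <= spec$thresholds[p])
  }
  scalar_series(vals, dt = traj$frame_spacing,
                provenance = list(coordinate = "contacts",
                                  n_pairs = nrow(spec$pairs)))
}

#' @rdname eval_coordinate
#' @export
eval_coordinate.distance_spec <- function(traj, spec) {
  check_spec_indices(traj, spec)
  vals <- numeric(n_frames(traj))
  for (p in seq_len(nrow(spec$pairs))) {
    if (spec$weights[p] == 0) next
    vals <- vals + spec$weights[p] *
      pair_dist_values(traj$coords, spec$pairs[p, 1] + 1L,
                       spec$pairs[p, 2] + 1L)
  }
  scalar_series(vals, dt = traj$frame_spacing,
                provenance = list(coordinate = "distances",
                                  n_pairs = nrow(spec$pairs)))
}

#' @rdname eval_coordinate
#' @export
eval_contact_coordinate <- function(traj, spec) {
  stopifnot(inherits(spec, "contact_spec"))
  eval_coordinate.contact_spec(traj, spec)
}

#' @rdname eval_coordinate
#' @export
eval_distance_coordinate <- function(traj, spec) {
  stopifnot(inherits(spec, "distance_spec"))
  eval_coordinate.distance_spec(traj, spec)
}

check_spec_indices <- function(traj, spec) {
  m <- n_atoms(traj)
  if (any(spec$pairs >= m))
    abort(sprintf("spec references atom index >= n_atoms = %d", m))
  invisible(TRUE)
}

#' Initialize a contacts coordinate from a native structure
#'
#' Builds the native-contact set: all pairs `(i, j)` with sequence separation
#' `j - i >= min_seq_sep` whose native distance is at most `cutoff`, signs all
#' +1, thresholds either a constant `r0` or proportional
#' `r0_ij = lambda * d_ij^nat`.
#'
#' @param native `M x 3` matrix, single-frame [atom_trajectory()], or path to
#'   a structure file.
#' @param cutoff native-distance cutoff defining a contact (Angstrom).
#' @param mode `"constant"` (threshold = `r0`) or `"proportional"`
#'   (threshold = `lambda * d^nat`).
#' @param r0 constant threshold (defaults to `cutoff`).
#' @param lambda proportionality factor for `mode = "proportional"`.
#' @param min_seq_sep minimum index separation `j - i` (0 for toy systems;
#'   use 3 for chain-indexed atoms).
#' @return a [contact_spec()].
#' @export
native_contact_init <- function(native, cutoff, mode = c("constant", "proportional"),
                                r0 = cutoff, lambda = 1.2, min_seq_sep = 0) {
  mode <- match.arg(mode)
  if (cutoff <= 0) abort("cutoff must be > 0")
  coords <- native_coords(native)
  m <- nrow(coords)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)  # i < j, 1-based
  keep <- (idx[, 2] - idx[, 1]) >= max(min_seq_sep, 1)
  idx <- idx[keep, , drop = FALSE]
  dnat <- sqrt(rowSums((coords[idx[, 1], , drop = FALSE] -
                          coords[idx[, 2], , drop = FALSE])^2))
  sel <- dnat <= cutoff
  if (!any(sel)) abort("no native contacts within cutoff")
  pairs <- cbind(idx[sel, 1] - 1L, idx[sel, 2] - 1L)
  dnat <- dnat[sel]
  if (mode == "constant")
    contact_spec(pairs, signs = rep(1, nrow(pairs)),
                 thresholds = rep(r0, nrow(pairs)), native_distances = dnat)
  else
    contact_spec(pairs, signs = rep(1, nrow(pairs)),
                 thresholds = lambda * dnat, native_distances = dnat,
                 lambda_scale = lambda)
}

#' Coordinate value of a single reference structure
#'
#' Evaluates a coordinate spec on one structure (typically the native one);
#' the value anchors the native basin in [objective_mfpt()],
#' [kinetics_report()] and [locate_transition_state()].
#'
#' @param spec a [contact_spec()] or [distance_spec()].
#' @param structure `M x 3` coordinate matrix, single-frame
#'   [atom_trajectory()], or file path.
#' @return the scalar coordinate value.
#' @export
native_coordinate_value <- function(spec, structure) {
  stopifnot(inherits(spec, "coordinate_spec"))
  eval_spec_single(spec, native_coords(structure))
}

# Coordinate value on a single structure (M x 3 matrix).
eval_spec_single <- function(spec, coords) {
  d <- sqrt(rowSums((coords[spec$pairs[, 1] + 1L, , drop = FALSE] -
                       coords[spec$pairs[, 2] + 1L, , drop = FALSE])^2))
  if (spec$family == "contacts") sum(spec$signs * (d <= spec$thresholds))
  else sum(spec$weights * d)
}

native_coords <- function(native) {
  if (is.character(native)) native <- read_atom_trajectory(native)
  if (inherits(native, "atom_trajectory"))
    return(matrix(native$coords[1, , ], ncol = 3))
  as.matrix(native)
}

#' Randomly scramble the signs of a contacts coordinate
#'
#' Produces the deliberately sub-optimal variant used as a bad-coordinate
#' reference: same pairs and thresholds, signs drawn uniformly from
#' `{-1, +1}`.
#'
#' @param spec a [contact_spec()].
#' @param seed integer seed or `NULL`.
#' @return a [contact_spec()] with randomized signs.
#' @export
scramble_signs <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "contact_spec"))
  with_seed(seed, {
    spec$signs <- sample(c(-1, 1), nrow(spec$pairs), replace = TRUE)
    spec$lambda_scale <- spec$lambda_scale  # thresholds untouched
    spec
  })
}

#' Read / write coordinate specs as JSON
#'
#' Serialization: `{"family": "contacts"|"distances", "pairs": [[i,j],...],
#' "signs": [...], "thresholds": [...], "weights": [...], "lambda": ...}`
#' with 0-based atom indices.
#'
#' @param spec a coordinate spec.
#' @param path file path.
#' @return `read_coordinate_spec()` returns the spec; the writer returns
#'   `path` invisibly.
#' @export
write_coordinate_spec <- function(spec, path) {
  stopifnot(inherits(spec, "coordinate_spec"))
  x <- list(family = spec$family,
            pairs = unname(apply(spec$pairs, 1, as.list)))
  if (spec$family == "contacts") {
    x$signs <- spec$signs
    x$thresholds <- spec$thresholds
    if (!is.null(spec$native_distances)) x$native_distances <- spec$native_distances
    if (!is.null(spec$lambda_scale)) x$lambda <- spec$lambda_scale
  } else {
    x$weights <- spec$weights
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coordinate_spec
#' @export
read_coordinate_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- if (is.matrix(x$pairs)) x$pairs else
    matrix(as.integer(unlist(x$pairs)), ncol = 2, byrow = TRUE)
  if (identical(x$family, "contacts"))
    contact_spec(pairs, x$signs, x$thresholds,
                 native_distances = x$native_distances,
                 lambda_scale = x$lambda)
  else if (identical(x$family, "distances"))
    distance_spec(pairs, x$weights)
  else abort(sprintf("unknown coordinate family '%s' in %s", x$family, path))
}
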