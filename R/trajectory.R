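#' Multi-frame atom trajectory
#'
#' Holds per-frame Cartesian coordinates (Angstrom) as an
#' `n_frames x n_atoms x 3` array plus the frame spacing in time units
#' (default 1: the saved-frame spacing is the unit of time downstream).
#'
#' @param coords numeric array `n_frames x n_atoms x 3`, or a single
#'   `n_atoms x 3` matrix (one frame).
#' @param frame_spacing time units between frames.
#' @param atom_names optional character vector of atom names (PDB output).
#' @return an `atom_trajectory` object.
#' @export
atom_trajectory <- function(coords, frame_spacing = 1, atom_names = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[3] != 3)
    abort("`coords` must be an n_frames x n_atoms x 3 array")
  if (!all(is.finite(coords))) abort("trajectory coordinates must be finite")
  if (dim(coords)[1] < 1 || dim(coords)[2] < 1)
    abort("trajectory needs at least one frame and one atom")
  m <- dim(coords)[2]
  if (is.null(atom_names)) atom_names <- rep("CA", m)
  structure(list(coords = coords, frame_spacing = frame_spacing,
                 atom_names = atom_names),
            class = "atom_trajectory")
}

#' @rdname atom_trajectory
#' @param x an `atom_trajectory`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname atom_trajectory
#' @export
n_atoms <- function(x) dim(x$coords)[2]

#' @export
print.atom_trajectory <- function(x, ...) {
  cat(sprintf("<atom_trajectory: %d frames x %d atoms, frame spacing %g>\n",
              n_frames(x), n_atoms(x), x$frame_spacing))
  invisible(x)
}

#' Read an atom trajectory from a multi-model PDB or extended XYZ file
#'
#' PDB files are parsed with bio3d (first chain, all models); XYZ files are
#' plain repeated blocks of `n`, comment, then `name x y z` lines.
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`; default guesses from the extension.
#' @param frame_spacing time units between frames.
#' @return an [atom_trajectory()].
#' @export
read_atom_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                                 frame_spacing = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz",
                     abort(sprintf("cannot guess trajectory format from '%s'", path)))
  }
  if (format == "pdb") read_pdb_trajectory(path, frame_spacing)
  else read_xyz_trajectory(path, frame_spacing)
}

read_pdb_trajectory <- function(path, frame_spacing = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                      # n_models x 3M matrix
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  m <- ncol(xyz) / 3
  if (m != round(m)) abort(sprintf("malformed PDB '%s': coordinate count not divisible by 3", path))
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, m, 3))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, 3 * m, by = 3), drop = FALSE]
  atom_trajectory(coords, frame_spacing, atom_names = pdb$atom$elety[seq_len(m)])
}

read_xyz_trajectory <- function(path, frame_spacing = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); names_1 <- NULL
  i <- 1L; fr <- 1L
  while (i <= length(lines)) {
    m <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(m) || m < 1)
      abort(sprintf("malformed XYZ '%s': expected atom count at line %d", path, i))
    if (i + 1L + m > length(lines))
      abort(sprintf("truncated XYZ '%s': frame %d incomplete", path, fr))
    block <- lines[(i + 2L):(i + 1L + m)]
    toks <- strsplit(trimws(block), "\\s+")
    nm <- vapply(toks, `[`, "", 1L)
    xyz <- suppressWarnings(
      t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))))
    if (anyNA(xyz))
      abort(sprintf("malformed XYZ '%s': non-numeric coordinates in frame %d", path, fr))
    if (fr == 1L) names_1 <- nm
    else if (length(nm) != length(names_1))
      abort(sprintf("inconsistent atom count in '%s' at frame %d", path, fr))
    frames[[fr]] <- xyz
    i <- i + 2L + m; fr <- fr + 1L
  }
  if (length(frames) == 0) abort(sprintf("empty XYZ file: %s", path))
  mm <- nrow(frames[[1]])
  coords <- array(NA_real_, c(length(frames), mm, 3))
  for (f in seq_along(frames)) {
    if (nrow(frames[[f]]) != mm)
      abort(sprintf("inconsistent atom count in '%s' at frame %d", path, f))
    coords[f, , ] <- frames[[f]]
  }
  atom_trajectory(coords, frame_spacing, atom_names = names_1)
}

#' Write an atom trajectory
#'
#' `write_xyz_trajectory()` writes extended XYZ (atom count, comment, then
#' `name x y z` per atom, repeated per frame); `write_pdb_trajectory()` writes
#' a multi-model PDB (`MODEL`/`ENDMDL` blocks of fixed-width `ATOM` records).
#'
#' @param traj an [atom_trajectory()].
#' @param path output file.
#' @param comment per-file comment for XYZ frame headers.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, comment = "difftrace") {
  stopifnot(inherits(traj, "atom_trajectory"))
  m <- n_atoms(traj)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(m), sprintf("%s frame %d", comment, f - 1L)), con)
    writeLines(sprintf("%-4s %17.10g %17.10g %17.10g", traj$atom_names,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz_trajectory
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "atom_trajectory"))
  m <- n_atoms(traj)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(m), substr(traj$atom_names, 1, 4), "GLY", seq_len(m),
      traj$coords[f, , 1], traj$coords[f, , 2], traj$coords[f, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
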