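#' Scalar reaction-coordinate time series
#'
#' A `scalar_series` is the object every profile computation consumes: the
#' projection of a trajectory onto a reaction coordinate, sampled at uniform
#' intervals.  It is a tibble with columns `frame` (0-based index) and
#' `value`, carrying the frame spacing `dt` (time units per frame; the
#' saved-frame spacing is the unit of time everywhere downstream) and a
#' free-form `provenance` list as attributes.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param dt time per frame (default 1; all downstream times are in these
#'   units).
#' @param provenance named list of metadata (seed, generator parameters, ...)
#'   recorded in file headers.
#' @return a `scalar_series` tibble.
#' @export
#' @examples
#' s <- scalar_series(cumsum(rnorm(100)))
#' series_values(s)[1:5]
scalar_series <- function(values, dt = 1, provenance = list()) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("a scalar_series needs at least 2 frames")
  if (!all(is.finite(values))) abort("scalar_series values must all be finite")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    abort("`dt` must be a single positive number")
  out <- tibble(frame = seq_along(values) - 1L, value = values)
  attr(out, "dt") <- as.numeric(dt)
  attr(out, "provenance") <- as.list(provenance)
  class(out) <- c("scalar_series", class(out))
  out
}

#' @rdname scalar_series
#' @param x object to convert / a `scalar_series`.
#' @export
as_scalar_series <- function(x, dt = 1, provenance = list()) {
  if (inherits(x, "scalar_series")) return(x)
  if (is.numeric(x)) return(scalar_series(x, dt = dt, provenance = provenance))
  if (is.data.frame(x) && "value" %in% names(x))
    return(scalar_series(x$value, dt = dt, provenance = provenance))
  abort("cannot interpret `x` as a scalar_series")
}

#' @rdname scalar_series
#' @export
series_values <- function(x) {
  stopifnot(inherits(x, "scalar_series"))
  x$value
}

#' @rdname scalar_series
#' @export
series_dt <- function(x) attr(x, "dt") %||% 1

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series: %d frames, dt = %g>\n", nrow(x), series_dt(x)))
  NextMethod()
}

# Apply a function to the values, preserving dt/provenance.
series_map <- function(x, f, note = NULL) {
  prov <- attr(x, "provenance")
  if (!is.null(note)) prov$transform <- c(prov$transform, note)
  scalar_series(f(series_values(x)), dt = series_dt(x), provenance = prov)
}

#' Read and write scalar series as TSV
#'
#' Two tab-separated columns (`frame`, `value`) preceded by `#` header lines
#' recording `dt` and provenance as `# key = value`.  Values round-trip at 17
#' significant digits (lossless for doubles).
#'
#' @param x a [scalar_series()].
#' @param path file path.
#' @return `read_series()` returns a `scalar_series`; `write_series()` returns
#'   `path` invisibly.
#' @export
write_series <- function(x, path) {
  stopifnot(inherits(x, "scalar_series"))
  prov <- attr(x, "provenance")
  hdr <- c("# difftrace scalar_series",
           sprintf("# dt = %.17g", series_dt(x)),
           vapply(names(prov), function(k)
             sprintf("# %s = %s", k, paste(format(prov[[k]], digits = 17),
                                           collapse = ",")),
             character(1)))
  body <- sprintf("%d\t%.17g", x$frame, x$value)
  writeLines(c(hdr, "frame\tvalue", body), path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort(sprintf("empty series file: %s", path))
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_.][A-Za-z0-9_.]*)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  dt <- 1
  if (!is.null(meta$dt)) {
    dt <- as.numeric(meta$dt)
    meta$dt <- NULL
  } else {
    warn(sprintf("no dt in header of %s; assuming dt = 1", path))
  }
  idx <- which(!is_hdr)
  if (length(idx) && grepl("^frame\\b", lines[idx[1]])) idx <- idx[-1]
  if (length(idx) == 0) abort(sprintf("no data rows in series file: %s", path))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  vals <- suppressWarnings(vapply(parts, function(p) as.numeric(p[2]), 1.0))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    abort(sprintf("non-numeric value in %s at line %d", path, idx[bad]))
  }
  scalar_series(vals, dt = dt, provenance = meta)
}
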