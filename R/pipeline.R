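#' Pipeline configuration
#'
#' Describes one full analysis run: project (or load) a scalar coordinate,
#' compute histogram/cut/diffusion profiles and the natural coordinate, the
#' anomalous-exponent profile, the transition-state MSD, and the Kramers
#' kinetics report, writing TSV/JSON artifacts plus a manifest.
#'
#' @param series path to a series TSV (exclusive with
#'   `trajectory`/`coordinate`).
#' @param trajectory path to a multi-model PDB or XYZ trajectory.
#' @param coordinate path to a coordinate-spec JSON (used with `trajectory`).
#' @param out_dir output directory (created if missing).
#' @param n_bins histogram bins.
#' @param k base cut stride.
#' @param k1,k2 strides for the exponent profile.
#' @param ts_half_width MSD origin-window half width, natural-coordinate
#'   units.
#' @param msd_max_lag largest MSD lag, frames.
#' @param n_boot bootstrap replicates for exponent standard errors.
#' @param seed seed recorded in every artifact and used for all randomness.
#' @return a `run_config` list.
#' @export
run_config <- function(series = NULL, trajectory = NULL, coordinate = NULL,
                       out_dir, n_bins = 32, k = 1, k1 = 1, k2 = 2,
                       ts_half_width = 0.5, msd_max_lag = 500, n_boot = 0,
                       seed = 1) {
  if (is.null(series) && is.null(trajectory))
    abort("run_config needs either a series or a trajectory input")
  if (!is.null(trajectory) && is.null(coordinate))
    abort("a trajectory input needs a coordinate spec")
  structure(list(series = series, trajectory = trajectory,
                 coordinate = coordinate, out_dir = out_dir, n_bins = n_bins,
                 k = k, k1 = k1, k2 = k2, ts_half_width = ts_half_width,
                 msd_max_lag = msd_max_lag, n_boot = n_boot, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' @param cfg a [run_config()].
#' @return (invisibly) the manifest list; artifacts are written under
#'   `cfg$out_dir`: `profiles.tsv`, `alpha.tsv`, `msd.tsv`, `kinetics.json`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$series, cfg$trajectory, cfg$coordinate))
    if (!file.exists(p)) abort(sprintf("input not found: %s", p))
  with_seed(cfg$seed, {
    series <- stage("project", {
      if (!is.null(cfg$series)) read_series(cfg$series)
      else eval_coordinate(read_atom_trajectory(cfg$trajectory),
                           read_coordinate_spec(cfg$coordinate))
    })
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(cfg$out_dir, c(profiles = "profiles.tsv",
                                      alpha = "alpha.tsv", msd = "msd.tsv",
                                      kinetics = "kinetics.json",
                                      manifest = "manifest.json"))
    names(paths) <- c("profiles", "alpha", "msd", "kinetics", "manifest")

    tbl <- stage("profile", profile_table(series, cfg$n_bins, cfg$k))
    write_profile_table(tbl, paths["profiles"])

    ap <- stage("alpha", alpha_profile(series, k1 = cfg$k1, k2 = cfg$k2,
                                       n_boot = cfg$n_boot))
    write_tsv_hdr(ap, paths["alpha"],
                  c(sprintf("# k1 = %d", cfg$k1), sprintf("# k2 = %d", cfg$k2),
                    sprintf("# seed = %s", cfg$seed)))

    kin <- stage("kinetics", kinetics_report(series, cfg$n_bins, cfg$k))
    write_kinetics(kin, paths["kinetics"])

    msd <- stage("msd", {
      nat <- natural_transform(series, n_bins = cfg$n_bins, k = cfg$k)
      y_ts <- apply_map(nat$map, kin$x_TS)
      msd_from_window(nat$series, y_ts, cfg$ts_half_width,
                      max_lag = min(cfg$msd_max_lag,
                                    nrow(series) %/% 10))
    })
    write_tsv_hdr(msd, paths["msd"],
                  c(sprintf("# level = %.17g", attr(msd, "level")),
                    sprintf("# gamma = %.6g", attr(msd, "gamma")),
                    sprintf("# alpha = %.6g", attr(msd, "alpha"))))

    i <- which.min(abs(ap$level - kin$x_TS))
    manifest <- list(
      inputs = Filter(Negate(is.null),
                      list(series = cfg$series, trajectory = cfg$trajectory,
                           coordinate = cfg$coordinate)),
      package_version = as.character(utils::packageVersion("difftrace")),
      seed = cfg$seed,
      config_hash = rlang::hash(unclass(cfg)),
      artifacts = as.list(paths[c("profiles", "alpha", "msd", "kinetics")]),
      summary = list(n_frames = nrow(series), x_TS = kin$x_TS,
                     barrier_height_kT = kin$barrier_height_kT,
                     n_events_est = kin$n_events_est,
                     alpha_TS = ap$alpha[i]))
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA)
    invisible(manifest)
  })
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e)
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
}

write_tsv_hdr <- function(tbl, path, hdr) {
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(as_tibble(tbl), path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}
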