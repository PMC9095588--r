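# File I/O, configuration, provenance and the umbrella pipeline.
#
# Conventions: multi-page TIFF for image data with a YAML sidecar carrying
# physical metadata (voxel sizes, frame interval, fitted radius); CSV for
# tables (comma separated, '.' decimal, mandatory header, '#' comment lines
# for metadata); JSON for defect annotations. Internally everything is in
# micrometres and seconds; nm/s appears only at presentation boundaries.

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a voxel stack or equirectangular sequence as multi-page TIFF
#'
#' Data are written as 32-bit pages together with a YAML sidecar
#' (`<path>.yaml`) recording the object kind, physical metadata, and the
#' affine intensity scale used to fit arbitrary values into TIFF sample
#' range (intensities round-trip to about 1 part in 1e9).
#'
#' @param x A [voxel_stack()] or [equirect_seq()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(x, path) {
  if (inherits(x, "voxel_stack")) {
    d <- dim(x$intensity)
    pages <- lapply(seq_len(d[3]), function(k) x$intensity[, , k])
    meta <- list(kind = "voxel_stack", voxel_um = as.numeric(x$voxel_um),
                 origin_um = as.numeric(x$origin_um),
                 frame_interval_s = x$frame_interval_s)
  } else if (inherits(x, "equirect_seq")) {
    pages <- lapply(x$maps, unclass)
    meta <- list(kind = "equirect_seq", times_s = as.numeric(x$times),
                 radius_um = x$geometry$radius,
                 center_um = as.numeric(x$geometry$center))
  } else stop("x must be a voxel_stack or an equirect_seq")
  # TIFF samples are stored scaled into [0, 1]; the affine scale lives in the
  # sidecar so arbitrary intensities round-trip. Data already in [0, 1] are
  # stored unscaled (lo = 0, hi = 1), so a sidecar-less read is still exact.
  rng <- range(unlist(lapply(pages, range)))
  lo <- min(0, rng[1L]); hi <- max(1, rng[2L])
  if (hi > lo) pages <- lapply(pages, function(p) (p - lo) / (hi - lo))
  meta$intensity_scale <- c(lo, hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a multi-page TIFF with physical metadata
#'
#' Metadata (what the pages are, voxel sizes or map times, sphere radius)
#' come from the YAML sidecar written by [write_tiff_stack()] or from the
#' explicit arguments; explicit arguments override the sidecar. Missing
#' required metadata is an error with a remediation hint.
#'
#' @param path TIFF path.
#' @param sidecar Optional sidecar path (default `<path>.yaml` when it
#'   exists).
#' @param kind `"voxel_stack"` or `"equirect_seq"`; required if no sidecar.
#' @param voxel_um,origin_um,frame_interval_s Stack metadata overrides.
#' @param radius_um,center_um,times_s Map-sequence metadata overrides.
#' @return A [voxel_stack()] or [equirect_seq()].
#' @export
read_tiff_stack <- function(path, sidecar = NULL, kind = NULL, voxel_um = NULL,
                            origin_um = NULL, frame_interval_s = NULL,
                            radius_um = NULL, center_um = NULL, times_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- sidecar %||% (if (file.exists(sidecar_path(path))) sidecar_path(path))
  meta <- if (!is.null(sidecar)) yaml::read_yaml(sidecar) else list()
  kind <- kind %||% meta$kind
  if (is.null(kind))
    stop("image kind unknown: supply `kind` or a YAML sidecar with a `kind` field")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims != dims[, 1L])) stop("mismatched page sizes in ", path)
  sc <- meta$intensity_scale
  if (!is.null(sc) && sc[2L] > sc[1L])
    pages <- lapply(pages, function(p) p * (sc[2L] - sc[1L]) + sc[1L])
  if (kind == "voxel_stack") {
    voxel_um <- voxel_um %||% meta$voxel_um
    if (is.null(voxel_um))
      stop("voxel size unknown: supply `voxel_um` or a sidecar (um per voxel, x/y/z)")
    arr <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
    voxel_stack(arr, voxel_um, origin_um = origin_um %||% meta$origin_um,
                frame_interval_s = frame_interval_s %||% meta$frame_interval_s)
  } else if (kind == "equirect_seq") {
    radius_um <- radius_um %||% meta$radius_um
    if (is.null(radius_um))
      stop("sphere radius unknown: supply `radius_um` or a sidecar with `radius_um`")
    g <- sphere_geometry(radius_um, center_um %||% meta$center_um %||% c(0, 0, 0))
    times <- times_s %||% meta$times_s %||% (seq_along(pages) - 1)
    equirect_seq(lapply(pages, equirect_map, geometry = g), times)
  } else stop("unknown kind: ", kind)
}

provenance_header <- function(seed = NULL, config = NULL) {
  # the hash covers the scientific configuration, not where it is written,
  # so reruns into different directories produce identical artifacts
  if (!is.null(config)) config <- config[setdiff(names(config), "outdir")]
  c(sprintf("# sphereglide %s", as.character(utils::packageVersion("sphereglide"))),
    if (!is.null(seed)) sprintf("# seed %s", format(seed)),
    if (!is.null(config)) sprintf("# config_hash %s", fnv1a(deparse(config))))
}

write_csv_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write track tables as CSV with provenance comments
#'
#' @param rows Data frame in the track schema of [read_tracks_csv()].
#' @param path Output path.
#' @param seed,config Optional provenance recorded as '#' comment lines.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(rows, path, seed = NULL, config = NULL) {
  write_csv_with_header(as.data.frame(rows), path, provenance_header(seed, config))
}

#' Read and validate a track table
#'
#' Schema (comma separated, '#' comments ignored): `track_id`, `frame`,
#' `time_s`, then `phi_rad`, `theta_rad` (equirect mode) or `x_um`, `y_um`,
#' `hemisphere` (confocal mode). Frames must be strictly increasing within
#' each track; all violations are collected into one itemized error.
#'
#' @param path CSV path.
#' @param mode `"equirect"` or `"confocal"`.
#' @return Validated data frame (rows ordered by track and frame).
#' @export
read_tracks_csv <- function(path, mode = c("equirect", "confocal")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "time_s",
            if (mode == "equirect") c("phi_rad", "theta_rad") else c("x_um", "y_um", "hemisphere"))
  problems <- character()
  miss <- setdiff(need, names(df))
  if (length(miss)) problems <- c(problems, paste("missing column(s):", paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), need)
  if (length(extra)) problems <- c(problems, paste("unknown column(s):", paste(extra, collapse = ", ")))
  if (!length(miss)) {
    for (id in unique(df$track_id)) {
      fr <- df$frame[df$track_id == id]
      if (any(diff(fr) <= 0))
        problems <- c(problems, sprintf("track %s: frames not strictly increasing", id))
    }
    if (mode == "equirect" &&
        (any(df$theta_rad < 0 | df$theta_rad > pi) || any(!is.finite(df$phi_rad))))
      problems <- c(problems, "theta_rad out of [0, pi] or non-finite phi_rad")
  }
  if (length(problems))
    stop("invalid track file ", path, ":\n  - ", paste(problems, collapse = "\n  - "))
  df[order(df$track_id, df$frame), , drop = FALSE]
}

#' Write defect annotations as JSON
#'
#' @param configs A [defect_configuration()] or list of them (a time
#'   series).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_defects_json <- function(configs, path) {
  if (inherits(configs, "defect_configuration")) configs <- list(configs)
  rows <- do.call(rbind, lapply(configs, function(cf) {
    sph <- cart_to_sph(cf$xyz, cf$geometry, tol_rel = 1e-3)
    data.frame(time_s = cf$time_s, charge = format_charge(cf$charge_half),
               phi_rad = sph$phi, theta_rad = sph$theta,
               covers_full_surface = cf$covers_full_surface)
  }))
  jsonlite::write_json(rows, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read defect annotations from JSON
#'
#' Expects a list of records with fields `time_s`, `charge` (`"+1/2"` etc.),
#' `phi_rad`, `theta_rad` and optionally `covers_full_surface`.
#'
#' @param path JSON path.
#' @param geometry A [sphere_geometry()].
#' @return List of [defect_configuration()]s, one per distinct time.
#' @export
read_defects_json <- function(path, geometry) {
  g <- assert_geometry(geometry)
  rows <- jsonlite::fromJSON(path)
  if (!nrow(rows)) stop("empty defect file: ", path)
  lapply(split(rows, rows$time_s), function(d)
    defect_configuration(d$charge, g, theta = d$theta_rad, phi = d$phi_rad,
                         time_s = d$time_s[1L],
                         covers_full_surface = isTRUE(d$covers_full_surface[1L])))
}

#' Run the analysis pipeline on a synthetic or stored scene
#'
#' Executes the configured stages and writes all artifacts (maps TIFF +
#' sidecar, ground-truth tracks CSV, defects JSON, speed and MSD CSVs,
#' pair-angle series, classification) under one output directory. Every
#' table carries provenance comment lines (package version, seed, config
#' hash), making a run reproducible from config + seed alone.
#'
#' @param config Named list (or YAML path) with fields: `seed` (required),
#'   `outdir` (required), `scene_kind` (one of the [fixture_suite()] kinds),
#'   `n_frames`, `dt_s`, `n_theta`, `n_phi`, and `stages` (subset of
#'   `c("simulate", "speed", "msd", "defects", "classify")`, default all).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config validation: `seed` is required")
  if (is.null(config$outdir)) stop("config validation: `outdir` is required")
  kind <- config$scene_kind %||% "stream"
  stages <- config$stages %||% c("simulate", "speed", "msd", "defects", "classify")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(config$seed, config)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  fx <- run_stage("simulate", {
    suite <- fixture_suite(seed = config$seed, n_frames = config$n_frames %||% 6L,
                           dt_s = config$dt_s %||% 60,
                           n_theta = config$n_theta %||% 90L,
                           n_phi = config$n_phi %||% 180L,
                           render = TRUE)
    if (!kind %in% names(suite)) stop("unknown scene_kind: ", kind)
    suite[[kind]]
  })
  out <- function(f) file.path(config$outdir, f)
  if ("simulate" %in% stages) {
    write_tiff_stack(fx$maps, out("maps.tif"))
    trk <- do.call(rbind, lapply(seq_along(fx$trajectories), function(i) {
      d <- as.data.frame(fx$trajectories[[i]])
      data.frame(track_id = i, frame = seq_len(nrow(d)), time_s = d$time_s,
                 phi_rad = d$phi_rad, theta_rad = d$theta_rad)
    }))
    if (!is.null(trk)) write_tracks_csv(trk, out("tracks.csv"), config$seed, config)
    if (!is.null(fx$defects)) write_defects_json(fx$defects, out("defects.json"))
    yaml::write_yaml(list(kind = fx$kind, label = fx$label, seed = config$seed),
                     out("ground_truth.yaml"))
  }
  all_trajs <- c(fx$trajectories, fx$defect_tracks)
  if ("speed" %in% stages && length(all_trajs)) {
    sp <- do.call(rbind, lapply(seq_along(all_trajs), function(i) {
      s <- instantaneous_speeds(all_trajs[[i]])
      data.frame(track_id = i, s)
    }))
    run_stage("speed", write_csv_with_header(sp, out("speeds.csv"), hdr))
  }
  if ("msd" %in% stages && length(all_trajs)) {
    ms <- do.call(rbind, lapply(seq_along(all_trajs), function(i)
      data.frame(track_id = i, as.data.frame(angular_msd(all_trajs[[i]])))))
    run_stage("msd", write_csv_with_header(ms, out("msd.csv"), hdr))
  }
  if ("defects" %in% stages && !is.null(fx$defect_tracks)) {
    series <- configuration_series(fx$defect_tracks)
    ph <- validate_poincare_hopf(fx$defects)
    run_stage("defects", {
      write_csv_with_header(as.data.frame(series), out("pair_angles.csv"),
                            c(hdr, sprintf("# sd_deg %.6g", attr(series, "sd_deg"))))
      writeLines(c(hdr, sprintf("poincare_hopf: %s", if (ph$pass) "pass" else "fail"),
                   ph$message), out("poincare_hopf.txt"))
    })
  }
  if ("classify" %in% stages) {
    run_stage("classify", {
      sp_str <- if (length(fx$trajectories))
        unlist(lapply(fx$trajectories, function(tr) instantaneous_speeds(tr)$speed_nm_s))
      sp_def <- if (!is.null(fx$defect_tracks))
        unlist(lapply(fx$defect_tracks, function(tr) instantaneous_speeds(tr)$speed_nm_s))
      cl <- classify_pattern(fx$maps, sp_str, fx$defects, sp_def)
      write_csv_with_header(
        data.frame(label = cl$label, as.data.frame(cl$features)),
        out("classification.csv"), hdr)
    })
  }
  invisible(config$outdir)
}
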