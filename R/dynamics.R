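# Trajectory dynamics: ingesting tracked positions, arc-length speeds,
# angular mean squared displacements, patch-correlation feature tracking on
# equirectangular map sequences, and time-averaged surface flow.

#' Build on-sphere trajectories from a planar track table
#'
#' Positions marked on an equirectangular projection (`phi_rad`,
#' `theta_rad`) or on a confocal plane (`x_um`, `y_um`, `hemisphere`,
#' relative to the sphere centre) are re-projected onto the vesicle sphere.
#'
#' @param rows Data frame with columns `time_s` plus, for `mode =
#'   "equirect"`: `phi_rad`, `theta_rad`; for `mode = "confocal"`: `x_um`,
#'   `y_um`, `hemisphere` (`"upper"`/`"lower"`). An optional `track_id`
#'   column splits rows into several trajectories.
#' @param mode `"equirect"` or `"confocal"`.
#' @param geometry A [sphere_geometry()]; the vesicle radius must be known
#'   for either re-projection.
#' @return A single [trajectory()] (one track) or a named list of
#'   trajectories (several `track_id`s).
#' @export
ingest_track <- function(rows, mode = c("equirect", "confocal"), geometry) {
  mode <- match.arg(mode)
  g <- assert_geometry(geometry)
  rows <- as.data.frame(rows)
  need <- c("time_s", if (mode == "equirect") c("phi_rad", "theta_rad")
            else c("x_um", "y_um", "hemisphere"))
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing track columns: ", paste(miss, collapse = ", "))
  one <- function(df) {
    df <- df[order(df$time_s), , drop = FALSE]
    xyz <- if (mode == "equirect") {
      sph_to_cart(df$theta_rad, df$phi_rad, g)
    } else {
      hemis <- as.character(df$hemisphere)
      bad <- !hemis %in% c("upper", "lower")
      if (any(bad)) stop("invalid hemisphere at row(s) ",
                         paste(utils::head(which(bad), 5L), collapse = ", "))
      out <- matrix(NA_real_, nrow(df), 3L)
      for (h in unique(hemis)) {
        i <- hemis == h
        out[i, ] <- tryCatch(confocal_to_sphere(df$x_um[i], df$y_um[i], g, h),
                             error = function(e) stop("row(s) ", paste(which(i), collapse = ","),
                                                      ": ", conditionMessage(e), call. = FALSE))
      }
      out
    }
    trajectory(df$time_s, xyz, g)
  }
  if ("track_id" %in% names(rows) && length(unique(rows$track_id)) > 1L) {
    lapply(split(rows, rows$track_id), one)
  } else one(rows)
}

#' Instantaneous arc-length speeds of a trajectory
#'
#' Elementwise [arc_speed()] over consecutive position pairs, reported in
#' nm/s. Requires a regular frame interval.
#'
#' @param traj A [trajectory()] with at least two points.
#' @param rel_tol Relative tolerance on frame-interval regularity.
#' @return Data frame of class `speed_series` with columns `time_s` (time of
#'   the later frame of each pair) and `speed_nm_s`; attribute `dt_s`.
#' @export
instantaneous_speeds <- function(traj, rel_tol = 1e-6) {
  if (!inherits(traj, "trajectory")) stop("traj must be a trajectory")
  n <- length(traj$times)
  if (n < 2L) stop("at least two points are needed for speeds")
  if (!is_regular_times(traj$times, rel_tol))
    stop("nonuniform frame interval; speeds require a regular dt")
  dt <- diff(traj$times)
  v <- arc_speed(traj$xyz[-n, , drop = FALSE], traj$xyz[-1L, , drop = FALSE],
                 dt, traj$geometry) * 1000
  structure(data.frame(time_s = traj$times[-1L], speed_nm_s = v),
            dt_s = mean(dt), class = c("speed_series", "data.frame"))
}

#' Mean and dispersion of an instantaneous speed series
#'
#' @param s A `speed_series` from [instantaneous_speeds()], or a numeric
#'   vector of speeds in nm/s.
#' @param window Optional time window `c(t0, t1)` in seconds (inclusive);
#'   e.g. the interval after a pattern has formed.
#' @return Named numeric vector `c(mean = , sd = )` in nm/s.
#' @export
mean_speed <- function(s, window = NULL) {
  if (inherits(s, "speed_series") || is.data.frame(s)) {
    t <- s$time_s; v <- s$speed_nm_s
  } else {
    v <- as.numeric(s); t <- seq_along(v)
  }
  if (!is.null(window)) {
    keep <- t >= window[1L] & t <= window[2L]
    v <- v[keep]
  }
  if (!length(v)) stop("empty speed window")
  c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Angular mean squared displacement of a trajectory
#'
#' Time-averaged MSD of the colatitude and azimuth components,
#' `<(theta(t+tau) - theta(t))^2>` and `<(phi(t+tau) - phi(t))^2>`, at lags
#' `tau = k * dt` with overlapping windows. The azimuth series is unwrapped
#' across the 0/2pi seam before differencing, and each lag difference is then
#' reduced to the bounded increment in `(-pi, pi]` so that, as on any closed
#' surface, the MSD saturates at long lags. Before saturation a uniform
#' rotation gives exactly `(omega * tau)^2`.
#'
#' @param traj A regular-interval [trajectory()] with at least three points.
#' @param max_lag_frames Largest lag in frames (default `n - 1`).
#' @param rel_tol Frame-interval regularity tolerance.
#' @return Data frame of class `angular_msd` with columns `lag_s`,
#'   `msd_theta`, `msd_phi` (rad^2) and `n` (pair count per lag), including
#'   the zero-lag row.
#' @export
angular_msd <- function(traj, max_lag_frames = NULL, rel_tol = 1e-6) {
  if (!inherits(traj, "trajectory")) stop("traj must be a trajectory")
  n <- length(traj$times)
  if (n < 3L) stop("at least three points are needed for an MSD")
  if (!is_regular_times(traj$times, rel_tol))
    stop("irregular sampling; the angular MSD requires a uniform frame interval")
  dt <- mean(diff(traj$times))
  sph <- cart_to_sph(traj$xyz, traj$geometry, tol_rel = 1e-3)
  theta <- sph$theta
  phi <- unwrap_azimuth(sph$phi)
  kmax <- min(max_lag_frames %||% (n - 1L), n - 1L)
  msd_t <- msd_p <- numeric(kmax)
  cnt <- integer(kmax)
  for (k in seq_len(kmax)) {
    dth <- theta[(1L + k):n] - theta[1L:(n - k)]
    dph <- phi[(1L + k):n] - phi[1L:(n - k)]
    dph <- ((dph + pi) %% (2 * pi)) - pi  # bounded increment on the circle
    msd_t[k] <- mean(dth^2)
    msd_p[k] <- mean(dph^2)
    cnt[k] <- n - k
  }
  structure(data.frame(lag_s = c(0, seq_len(kmax) * dt),
                       msd_theta = c(0, msd_t), msd_phi = c(0, msd_p),
                       n = c(n, cnt)),
            dt_s = dt, class = c("angular_msd", "data.frame"))
}

#' Log-log scaling exponent of an angular MSD
#'
#' Least-squares slope of `log(MSD)` versus `log(tau)` over a lag range.
#' Slope 2 indicates ballistic circulation, slope 1 diffusive wandering; at
#' lags beyond saturation the slope drops below 1.
#'
#' @param m An [angular_msd()] result.
#' @param component `"phi"` or `"theta"`.
#' @param lag_range Optional `c(min, max)` lag in seconds (inclusive). The
#'   default is the first quartile of positive lags, targeting the
#'   short-time regime.
#' @return Fitted exponent (numeric scalar) with attribute `n_lags`.
#' @export
msd_scaling_exponent <- function(m, component = c("phi", "theta"), lag_range = NULL) {
  if (!inherits(m, "angular_msd")) stop("m must be an angular_msd")
  component <- match.arg(component)
  lag <- m$lag_s
  y <- if (component == "phi") m$msd_phi else m$msd_theta
  pos <- lag > 0
  if (is.null(lag_range)) lag_range <- c(0, stats::quantile(lag[pos], 0.25, names = FALSE))
  keep <- pos & lag >= lag_range[1L] & lag <= lag_range[2L]
  if (sum(keep) < 3L) stop("need at least three lags in the fit range")
  if (any(y[keep] <= 0)) stop("zero MSD values in the fit range; log slope undefined")
  fit <- stats::lm(log(y[keep]) ~ log(lag[keep]))
  structure(unname(stats::coef(fit)[2L]), n_lags = sum(keep))
}

# ---- patch cross-correlation feature tracking -------------------------------

# Extract a (2h+1)^2 patch centred at (row, col) with phi-periodic column
# wrap; returns NULL when the patch would cross a theta edge.
extract_patch <- function(M, row, col, h) {
  nr <- nrow(M); nc <- ncol(M)
  if (row - h < 1L || row + h > nr) return(NULL)
  cols <- ((col - h - 1L):(col + h - 1L)) %% nc + 1L
  M[(row - h):(row + h), cols, drop = FALSE]
}

ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# Local maxima of a map above a response floor, with non-maximum suppression
# at the given pixel radius and phi wrap.
find_local_maxima <- function(M, min_response, exclude_border, suppress_radius) {
  nr <- nrow(M); nc <- ncol(M)
  cand <- which(M >= min_response, arr.ind = TRUE)
  cand <- cand[cand[, 1L] > exclude_border & cand[, 1L] <= nr - exclude_border, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1L]; c0 <- cand[i, 2L]
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    all(vapply(seq_len(nrow(nb)), function(j) {
      rr <- r + nb$dr[j]; cc <- (c0 + nb$dc[j] - 1L) %% nc + 1L
      M[r, c0] >= M[rr, cc]
    }, logical(1L)))
  }, logical(1L))
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  ord <- order(M[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    ddr <- abs(prev[, 1L] - cand[i, 1L])
    ddc <- abs(prev[, 2L] - cand[i, 2L])
    ddc <- pmin(ddc, nc - ddc)
    keep[i] <- all(pmax(ddr, ddc) > suppress_radius)
  }
  cand[keep, , drop = FALSE]
}

#' Track intensity features across an equirectangular map sequence
#'
#' A deterministic sparse feature tracker: features are seeded at local
#' intensity maxima of the first frame above `min_response`, and each is
#' followed frame to frame by maximizing the normalized cross-correlation of
#' a square patch within a search radius, with phi-periodic wrapping of the
#' search window. A track ends when the best correlation falls below
#' `corr_floor`.
#'
#' @param maps An [equirect_seq()] with at least two frames.
#' @param patch_size Odd patch edge length in pixels (default 15).
#' @param search_radius Search radius in pixels per frame step (default 10).
#' @param min_response Seeding intensity floor; default half the first
#'   frame's maximum.
#' @param corr_floor Correlation below which a track terminates (default
#'   0.5).
#' @return List of class `feature_tracks`; each element is a data frame with
#'   columns `frame`, `time_s`, `row`, `col`, `theta_rad`, `phi_rad`.
#'   Featureless input yields an empty list.
#' @export
track_features <- function(maps, patch_size = 15L, search_radius = 10L,
                           min_response = NULL, corr_floor = 0.5) {
  if (!inherits(maps, "equirect_seq")) stop("maps must be an equirect_seq")
  if (length(maps$maps) < 2L) stop("feature tracking needs at least two frames")
  if (patch_size %% 2L != 1L) stop("patch_size must be odd")
  h <- (patch_size - 1L) %/% 2L
  M1 <- unclass(maps$maps[[1L]])
  nr <- nrow(M1); nc <- ncol(M1)
  min_response <- min_response %||% (0.5 * max(M1))
  seeds <- find_local_maxima(M1, min_response, exclude_border = h + search_radius,
                             suppress_radius = patch_size)
  tracks <- list()
  for (s in seq_len(nrow(seeds))) {
    row <- seeds[s, 1L]; col <- seeds[s, 2L]
    pos <- data.frame(frame = 1L, time_s = maps$times[1L], row = row, col = col)
    tpl <- extract_patch(M1, row, col, h)
    for (f in 2L:length(maps$maps)) {
      M <- unclass(maps$maps[[f]])
      best <- -Inf; brow <- NA_integer_; bcol <- NA_integer_
      for (dr in -search_radius:search_radius) {
        rr <- row + dr
        if (rr - h < 1L || rr + h > nr) next
        for (dc in -search_radius:search_radius) {
          cc <- (col + dc - 1L) %% nc + 1L
          cand <- extract_patch(M, rr, cc, h)
          v <- ncc(as.numeric(tpl), as.numeric(cand))
          if (v > best) { best <- v; brow <- rr; bcol <- cc }
        }
      }
      if (!is.finite(best) || best < corr_floor) break
      row <- brow; col <- bcol
      pos <- rbind(pos, data.frame(frame = f, time_s = maps$times[f], row = row, col = col))
      tpl <- extract_patch(M, row, col, h)
    }
    pos$theta_rad <- (pos$row - 0.5) * pi / nr
    pos$phi_rad <- (pos$col - 0.5) * 2 * pi / nc
    tracks[[length(tracks) + 1L]] <- pos
  }
  structure(tracks, class = "feature_tracks", geometry = maps$geometry)
}

#' Time-averaged flow field from feature tracks
#'
#' Each track step is lifted onto the sphere through the polar-to-Cartesian
#' map, its speed measured by the arc-length formula, and its tangential
#' velocity components (along colatitude and azimuth) averaged on a coarse
#' `(theta, phi)` grid. The mean intensity projection over time accompanies
#' the vectors, mirroring time-averaged optical-flow overlays.
#'
#' @param maps An [equirect_seq()].
#' @param tracks A `feature_tracks` object from [track_features()], or a
#'   list of data frames with `time_s`, `theta_rad`, `phi_rad` columns.
#' @param geometry A [sphere_geometry()]; defaults to the sequence geometry.
#' @param n_theta_cells,n_phi_cells Flow grid resolution.
#' @return List of class `flow_field` with `mean_map` (an [equirect_map()])
#'   and `flow` (data frame: cell centres `theta_rad`, `phi_rad`, mean
#'   tangential velocities `v_theta_nm_s`, `v_phi_nm_s`, mean arc `speed_nm_s`,
#'   step count `n`).
#' @export
time_averaged_flow <- function(maps, tracks, geometry = NULL,
                               n_theta_cells = 6L, n_phi_cells = 12L) {
  if (!inherits(maps, "equirect_seq")) stop("maps must be an equirect_seq")
  if (!length(tracks)) stop("tracks must be nonempty")
  g <- assert_geometry(geometry %||% maps$geometry)
  mean_map <- equirect_map(Reduce(`+`, lapply(maps$maps, unclass)) / length(maps$maps), g)
  steps <- list()
  for (tr in tracks) {
    if (nrow(tr) < 2L) next
    xyz <- sph_to_cart(tr$theta_rad, tr$phi_rad, g)
    n <- nrow(tr)
    dt <- diff(tr$time_s)
    sp <- arc_speed(xyz[-n, , drop = FALSE], xyz[-1L, , drop = FALSE], dt, g) * 1000
    dth <- diff(tr$theta_rad)
    dph <- diff(unwrap_azimuth(tr$phi_rad))
    thm <- (tr$theta_rad[-n] + tr$theta_rad[-1L]) / 2
    steps[[length(steps) + 1L]] <- data.frame(
      theta = thm,
      phi = (tr$phi_rad[-n] + dph / 2) %% (2 * pi),
      v_theta = 1000 * g$radius * dth / dt,
      v_phi = 1000 * g$radius * sin(thm) * dph / dt,
      speed = sp)
  }
  if (!length(steps)) stop("tracks contain no steps")
  st <- do.call(rbind, steps)
  it <- pmin(pmax(ceiling(st$theta / (pi / n_theta_cells)), 1L), n_theta_cells)
  ip <- pmin(pmax(ceiling(st$phi / (2 * pi / n_phi_cells)), 1L), n_phi_cells)
  cell <- interaction(it, ip, drop = TRUE)
  agg <- do.call(rbind, lapply(split(st, cell), function(d) {
    data.frame(v_theta_nm_s = mean(d$v_theta), v_phi_nm_s = mean(d$v_phi),
               speed_nm_s = mean(d$speed), n = nrow(d))
  }))
  idx <- do.call(rbind, strsplit(rownames(agg), ".", fixed = TRUE))
  flow <- data.frame(theta_rad = (as.integer(idx[, 1L]) - 0.5) * pi / n_theta_cells,
                     phi_rad = (as.integer(idx[, 2L]) - 0.5) * 2 * pi / n_phi_cells,
                     agg, row.names = NULL)
  structure(list(mean_map = mean_map, flow = flow), class = "flow_field")
}

#' Overall mean speed of a flow field
#'
#' Step-count-weighted mean of per-cell arc speeds, in nm/s.
#'
#' @param flow A `flow_field` from [time_averaged_flow()].
#' @return Numeric scalar (nm/s).
#' @export
flow_mean_speed <- function(flow) {
  if (!inherits(flow, "flow_field")) stop("flow must be a flow_field")
  stats::weighted.mean(flow$flow$speed_nm_s, flow$flow$n)
}
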