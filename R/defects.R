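# Topological defect bookkeeping: charges, Poincare-Hopf accounting, pair
# angles and tetrahedral/planar configuration classification. On a sphere
# any orientation field covering the full surface must carry total charge
# +2; fully covered vesicles accommodate it with either two +1 pole defects
# (bands) or four +1/2 defects (jammed states).

# Charges are held internally in integer half-units (x2) so sums are exact.
CHARGE_LABELS <- c("+1/2" = 1L, "-1/2" = -1L, "+1" = 2L, "-1" = -2L)

parse_charge <- function(charge) {
  if (is.character(charge)) {
    unknown <- !charge %in% names(CHARGE_LABELS)
    if (any(unknown)) stop("unknown charge label(s): ", paste(unique(charge[unknown]), collapse = ", "))
    return(unname(CHARGE_LABELS[charge]))
  }
  half <- 2 * as.numeric(charge)
  if (any(abs(half - round(half)) > 1e-9) || any(!round(half) %in% CHARGE_LABELS))
    stop("charges must be one of +1/2, -1/2, +1, -1")
  as.integer(round(half))
}

format_charge <- function(half) names(CHARGE_LABELS)[match(half, CHARGE_LABELS)]

#' Configuration of charged point defects on a sphere
#'
#' A set of topological defects at a common time. Positions may be given as
#' spherical angles or as on-sphere Cartesian points.
#'
#' @param charges Character labels (`"+1/2"`, `"-1/2"`, `"+1"`, `"-1"`) or
#'   the equivalent numeric charges.
#' @param geometry A [sphere_geometry()].
#' @param theta,phi Defect colatitudes/azimuths in radians (alternative to
#'   `xyz`).
#' @param xyz n x 3 matrix of on-sphere positions in micrometres.
#' @param time_s Common observation time (seconds).
#' @param covers_full_surface Logical ground-truth flag: does the orientation
#'   field extend over the whole sphere? Only fully covering configurations
#'   are bound by the Poincare-Hopf constraint.
#' @return Object of class `defect_configuration`.
#' @export
defect_configuration <- function(charges, geometry, theta = NULL, phi = NULL,
                                 xyz = NULL, time_s = 0,
                                 covers_full_surface = TRUE) {
  g <- assert_geometry(geometry)
  half <- parse_charge(charges)
  if (!length(half)) stop("a defect configuration must be nonempty")
  if (is.null(xyz)) {
    if (is.null(theta) || is.null(phi)) stop("supply either xyz or theta and phi")
    xyz <- sph_to_cart(theta, phi, g)
  } else {
    xyz <- as_points(xyz)
    assert_on_sphere(xyz, g, tol_rel = 1e-3, what = "defect position")
  }
  if (nrow(xyz) != length(half)) stop("one position per charge required")
  structure(list(xyz = xyz, charge_half = half, time_s = as.numeric(time_s),
                 geometry = g, covers_full_surface = isTRUE(covers_full_surface)),
            class = "defect_configuration")
}

#' @export
print.defect_configuration <- function(x, ...) {
  cat(sprintf("defect_configuration: %d defect(s) [%s], total charge %+g, %s\n",
              length(x$charge_half), paste(format_charge(x$charge_half), collapse = ", "),
              total_charge(x),
              if (x$covers_full_surface) "full surface coverage" else "partial coverage"))
  invisible(x)
}

#' Pair angles of a defect configuration
#'
#' The angle between radii from the vesicle centre to each unordered defect
#' pair, in degrees, ordered lexicographically by defect index (for four
#' defects: 12, 13, 14, 23, 24, 34).
#'
#' @param config A [defect_configuration()] with at least two defects.
#' @return Numeric vector of pair angles in `[0, 180]` degrees.
#' @export
pair_angles <- function(config) {
  if (!inherits(config, "defect_configuration")) stop("config must be a defect_configuration")
  n <- nrow(config$xyz)
  if (n < 2L) stop("at least two defects are needed for pair angles")
  idx <- utils::combn(n, 2L)
  ang <- central_angle(config$xyz[idx[1L, ], , drop = FALSE],
                       config$xyz[idx[2L, ], , drop = FALSE],
                       config$geometry, tol_rel = 1e-3)
  ang * 180 / pi
}

#' Mean pair angle of a defect configuration
#'
#' Arithmetic mean of the `n(n-1)/2` pair angles. Reference values for four
#' defects: 109.47 degrees (regular tetrahedron, `acos(-1/3)`) and 120
#' degrees (equally spaced on a great circle).
#'
#' @param config A [defect_configuration()] with at least two defects.
#' @return Mean pair angle in degrees.
#' @export
mean_pair_angle <- function(config) mean(pair_angles(config))

#' Total topological charge
#'
#' Exact sum of defect charges, computed in integer half-units so no
#' floating-point accumulation occurs.
#'
#' @param config A [defect_configuration()].
#' @return Signed half-integer (numeric), e.g. `+2` for four +1/2 defects.
#' @export
total_charge <- function(config) {
  if (!inherits(config, "defect_configuration")) stop("config must be a defect_configuration")
  sum(config$charge_half) / 2
}

#' Poincare-Hopf validation
#'
#' A configuration whose orientation field covers the full sphere must carry
#' total charge +2; partially covering patterns (streams, vortices, partial
#' jams) are not bound by this constraint and always pass.
#'
#' @param config A [defect_configuration()].
#' @return List with `pass` (logical) and `message`.
#' @export
validate_poincare_hopf <- function(config) {
  if (!inherits(config, "defect_configuration")) stop("config must be a defect_configuration")
  q <- total_charge(config)
  if (!config$covers_full_surface) {
    return(list(pass = TRUE,
                message = sprintf("partial coverage: total charge %+g unconstrained", q)))
  }
  if (q == 2) list(pass = TRUE, message = "full coverage with total charge +2")
  else list(pass = FALSE,
            message = sprintf("full coverage requires total charge +2, found %+g", q))
}

TETRAHEDRAL_ANGLE <- acos(-1 / 3) * 180 / pi  # 109.4712...
PLANAR_ANGLE <- 120

#' Classify a four-defect configuration by its mean pair angle
#'
#' @param mean_angle Mean pair angle in degrees.
#' @param tol Tolerance in degrees; must be positive and smaller than half
#'   the tetrahedral-planar reference gap (about 5.26 degrees) so the two
#'   classes cannot overlap.
#' @return `"tetrahedral"`, `"planar"` or `"intermediate"`.
#' @export
classify_configuration <- function(mean_angle, tol = 2) {
  half_gap <- (PLANAR_ANGLE - TETRAHEDRAL_ANGLE) / 2
  if (!is.numeric(tol) || tol <= 0 || tol >= half_gap)
    stop(sprintf("tol must be in (0, %.2f) degrees to keep the classes disjoint", half_gap))
  if (abs(mean_angle - TETRAHEDRAL_ANGLE) <= tol) "tetrahedral"
  else if (abs(mean_angle - PLANAR_ANGLE) <= tol) "planar"
  else "intermediate"
}

#' Reference four-defect configurations
#'
#' Four +1/2 defects at the vertices of a regular tetrahedron inscribed in
#' the sphere, or equally spaced on the equatorial great circle (planar).
#'
#' @param type `"tetrahedral"` or `"planar"`.
#' @param geometry A [sphere_geometry()].
#' @param covers_full_surface Passed to [defect_configuration()].
#' @return A [defect_configuration()] of four +1/2 defects.
#' @export
reference_configuration <- function(type = c("tetrahedral", "planar"),
                                    geometry = sphere_geometry(18),
                                    covers_full_surface = TRUE) {
  type <- match.arg(type)
  g <- assert_geometry(geometry)
  u <- if (type == "tetrahedral") {
    matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4L, 3L, byrow = TRUE) / sqrt(3)
  } else {
    cbind(cos(c(0, pi / 2, pi, 3 * pi / 2)), sin(c(0, pi / 2, pi, 3 * pi / 2)), 0)
  }
  defect_configuration(rep("+1/2", 4L), g, xyz = sweep(g$radius * u, 2L, g$center, "+"),
                       covers_full_surface = covers_full_surface)
}

#' Pair-angle time series of four tracked defects
#'
#' Per-frame mean pair angle of four defect trajectories on a common time
#' base, with the temporal standard deviation as a stability metric (a
#' jammed state stays near one configuration; active nematic shells instead
#' oscillate between tetrahedral and planar arrangements).
#'
#' @param defect_tracks List of four [trajectory()] objects with identical
#'   times.
#' @param charges Charges of the four defects (default four +1/2).
#' @param covers_full_surface Passed through to per-frame configurations.
#' @return Data frame of class `pair_angle_series` with columns `time_s` and
#'   `mean_angle_deg`; attributes `sd_deg` (temporal std of the mean pair
#'   angle) and `pair_angles_deg` (frames x 6 matrix).
#' @export
configuration_series <- function(defect_tracks, charges = rep("+1/2", 4L),
                                 covers_full_surface = TRUE) {
  if (length(defect_tracks) != 4L) stop("four defect tracks are required")
  if (!all(vapply(defect_tracks, inherits, logical(1L), "trajectory")))
    stop("defect_tracks must be trajectory objects")
  times <- defect_tracks[[1L]]$times
  same <- vapply(defect_tracks, function(tr)
    length(tr$times) == length(times) && all(abs(tr$times - times) < 1e-9), logical(1L))
  if (!all(same)) stop("defect tracks have mismatched time bases")
  g <- defect_tracks[[1L]]$geometry
  angs <- t(vapply(seq_along(times), function(i) {
    xyz <- do.call(rbind, lapply(defect_tracks, function(tr) tr$xyz[i, ]))
    pair_angles(defect_configuration(charges, g, xyz = xyz, time_s = times[i],
                                     covers_full_surface = covers_full_surface))
  }, numeric(6L)))
  mean_ang <- rowMeans(angs)
  structure(data.frame(time_s = times, mean_angle_deg = mean_ang),
            sd_deg = stats::sd(mean_ang), pair_angles_deg = angs,
            class = c("pair_angle_series", "data.frame"))
}
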