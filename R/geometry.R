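# Sphere geometry: coordinate conventions, mappings and metric quantities.
#
# Conventions used throughout the package:
#   * theta is the colatitude (polar angle) measured from the +z pole,
#     theta in [0, pi]; the equator is theta = pi/2.
#   * phi is the azimuth, phi in [0, 2*pi), half-open.
#   * Cartesian positions are in micrometres in the lab frame; the vesicle
#     centre is carried by the `sphere_geometry` object.
#   * At the poles (sin(theta) ~ 0) the azimuth is undefined; it is returned
#     as 0 by convention so outputs stay deterministic.

#' Sphere geometry of a vesicle
#'
#' Centre and radius of the (fitted) spherical vesicle on whose inner surface
#' structures move. All metric quantities (arc lengths, speeds, pair angles)
#' are computed relative to this sphere.
#'
#' @param radius Sphere radius in micrometres (> 0). Giant unilamellar
#'   vesicles in this assay have radii of order 18 um.
#' @param center Numeric 3-vector, sphere centre in micrometres.
#' @return An object of class `sphere_geometry` with elements `center` and
#'   `radius`.
#' @examples
#' g <- sphere_geometry(18)
#' g$radius
#' @export
sphere_geometry <- function(radius, center = c(0, 0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("radius must be a single positive finite number (micrometres)")
  if (!is.numeric(center) || length(center) != 3L || !all(is.finite(center)))
    stop("center must be a finite numeric 3-vector")
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "sphere_geometry")
}

#' @export
print.sphere_geometry <- function(x, ...) {
  cat(sprintf("sphere_geometry: R = %.4g um, center = (%.4g, %.4g, %.4g) um\n",
              x$radius, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

assert_geometry <- function(g) {
  if (!inherits(g, "sphere_geometry")) stop("geometry must be a sphere_geometry object")
  g
}

# Radii of points relative to the sphere centre.
radial_dist <- function(p, g) {
  p <- as_points(p)
  sqrt((p[, 1] - g$center[1])^2 + (p[, 2] - g$center[2])^2 + (p[, 3] - g$center[3])^2)
}

assert_on_sphere <- function(p, g, tol_rel = 1e-6, what = "point") {
  r <- radial_dist(p, g)
  bad <- abs(r - g$radius) > tol_rel * g$radius
  if (any(bad))
    stop(sprintf("%s off sphere: |r - R| up to %.3g um exceeds tolerance %.3g um (rows %s)",
                 what, max(abs(r - g$radius)), tol_rel * g$radius,
                 paste(utils::head(which(bad), 5L), collapse = ", ")))
  invisible(r)
}

#' Map spherical coordinates to Cartesian positions on a sphere
#'
#' Applies `r = center + R * (cos(phi) sin(theta), sin(phi) sin(theta),
#' cos(theta))`, the re-projection used to lift positions marked on an
#' equirectangular projection back onto the vesicle surface.
#'
#' @param theta Colatitude(s) in radians, in `[0, pi]`.
#' @param phi Azimuth(s) in radians; values are wrapped into `[0, 2*pi)`.
#' @param geometry A [sphere_geometry()].
#' @return An n x 3 matrix of Cartesian positions (micrometres).
#' @examples
#' sph_to_cart(pi / 2, 0, sphere_geometry(1))  # (1, 0, 0)
#' @export
sph_to_cart <- function(theta, phi, geometry) {
  g <- assert_geometry(geometry)
  theta <- as.numeric(theta); phi <- as.numeric(phi)
  if (length(phi) == 1L) phi <- rep(phi, length(theta))
  if (length(theta) != length(phi)) stop("theta and phi must have equal length")
  if (!all(is.finite(theta)) || !all(is.finite(phi))) stop("angles must be finite")
  if (any(theta < -1e-12 | theta > pi + 1e-12))
    stop("theta (colatitude) must lie in [0, pi]")
  theta <- clamp(theta, 0, pi)
  phi <- phi %% (2 * pi)
  u <- cbind(cos(phi) * sin(theta), sin(phi) * sin(theta), cos(theta))
  sweep(g$radius * u, 2L, g$center, "+")
}

#' Map on-sphere Cartesian positions to spherical coordinates
#'
#' Inverse of [sph_to_cart()]. Points must lie on the sphere within
#' `tol_rel * R`; at the poles the azimuth is returned as 0 by convention.
#'
#' @param p Point (length-3 vector) or n x 3 matrix, micrometres.
#' @param geometry A [sphere_geometry()].
#' @param tol_rel Relative on-sphere tolerance (default 1e-6).
#' @return A data frame with columns `theta` and `phi` (radians).
#' @export
cart_to_sph <- function(p, geometry, tol_rel = 1e-6) {
  g <- assert_geometry(geometry)
  p <- as_points(p)
  r <- assert_on_sphere(p, g, tol_rel = tol_rel)
  v <- sweep(p, 2L, g$center)
  theta <- acos(clamp(v[, 3] / r, -1, 1))
  phi <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  phi[sin(theta) < 1e-12] <- 0  # pole convention
  data.frame(theta = theta, phi = phi)
}

#' Lift a confocal-plane position onto the sphere
#'
#' For a point `(x, y)` marked on a confocal projection (coordinates relative
#' to the sphere centre), the on-sphere position is
#' `(x, y, +/- sqrt(R^2 - x^2 - y^2))`, the sign set by the hemisphere the
#' plane images.
#'
#' @param x,y In-plane coordinates in micrometres, relative to the sphere
#'   centre axis.
#' @param geometry A [sphere_geometry()].
#' @param hemisphere `"upper"` (z >= centre) or `"lower"`.
#' @return An n x 3 matrix of Cartesian positions (micrometres, lab frame).
#' @export
confocal_to_sphere <- function(x, y, geometry, hemisphere = c("upper", "lower")) {
  g <- assert_geometry(geometry)
  hemisphere <- match.arg(hemisphere)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d2 <- x^2 + y^2
  out <- d2 > g$radius^2 * (1 + 1e-12)
  if (any(out))
    stop(sprintf("confocal point(s) outside projected disk (x^2 + y^2 > R^2) at rows %s",
                 paste(utils::head(which(out), 5L), collapse = ", ")))
  z <- sqrt(pmax(g$radius^2 - d2, 0))
  if (hemisphere == "lower") z <- -z
  sweep(cbind(x, y, z), 2L, g$center, "+")
}

#' Central angle between two on-sphere points
#'
#' Angle at the sphere centre between the radii through `p1` and `p2`,
#' computed as `atan2(|v1 x v2|, v1 . v2)`. This form is numerically stable
#' for nearly coincident points (nanometre steps on an 18 um sphere), where
#' the bare `acos` of the normalized dot product loses precision.
#'
#' @param p1,p2 Points (length-3 vectors or n x 3 matrices), micrometres.
#' @param geometry A [sphere_geometry()].
#' @param tol_rel On-sphere tolerance passed to validation.
#' @return Central angle(s) in radians, in `[0, pi]`.
#' @export
central_angle <- function(p1, p2, geometry, tol_rel = 1e-6) {
  g <- assert_geometry(geometry)
  p1 <- as_points(p1); p2 <- as_points(p2)
  if (nrow(p1) == 1L && nrow(p2) > 1L) p1 <- p1[rep(1L, nrow(p2)), , drop = FALSE]
  if (nrow(p2) == 1L && nrow(p1) > 1L) p2 <- p2[rep(1L, nrow(p1)), , drop = FALSE]
  if (nrow(p1) != nrow(p2)) stop("p1 and p2 must have matching numbers of points")
  assert_on_sphere(p1, g, tol_rel, "p1"); assert_on_sphere(p2, g, tol_rel, "p2")
  v1 <- sweep(p1, 2L, g$center); v2 <- sweep(p2, 2L, g$center)
  cx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
  cy <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
  cz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  atan2(sqrt(cx^2 + cy^2 + cz^2), rowSums(v1 * v2))
}

#' Arc-length speed between consecutive on-sphere positions
#'
#' The instantaneous speed of a tracked structure: the great-circle arc
#' length between two consecutive positions divided by the frame interval,
#' `v = R * acos(r_i . r_{i+1} / R^2) / dt` (evaluated through the stable
#' [central_angle()] form).
#'
#' @param p1,p2 Consecutive positions on the sphere (micrometres).
#' @param dt Frame interval in seconds (> 0).
#' @param geometry A [sphere_geometry()].
#' @return Speed(s) in micrometres per second (non-negative).
#' @examples
#' g <- sphere_geometry(18)
#' arc_speed(c(18, 0, 0), c(0, 18, 0), 60, g)  # quarter great circle in 60 s
#' @export
arc_speed <- function(p1, p2, dt, geometry) {
  if (!is.numeric(dt) || any(!is.finite(dt)) || any(dt <= 0))
    stop("dt must be positive and finite (seconds)")
  geometry$radius * central_angle(p1, p2, geometry) / dt
}

#' Unwrap an azimuth sequence across the 0/2pi seam
#'
#' Removes artificial 2*pi jumps from a sampled azimuth series so that
#' successive differences have magnitude at most pi. The first element is
#' unchanged and re-wrapping modulo 2*pi recovers the input.
#'
#' @param phi Numeric vector of azimuths in radians (nonempty).
#' @return Numeric vector of unwrapped azimuths.
#' @examples
#' unwrap_azimuth(c(0.1, 6.2, 0.2))
#' @export
unwrap_azimuth <- function(phi) {
  if (length(phi) == 0L) stop("phi must be nonempty")
  if (!all(is.finite(phi))) stop("phi must be finite")
  if (length(phi) == 1L) return(phi)
  d <- diff(phi)
  d <- ((d + pi) %% (2 * pi)) - pi
  phi[1L] + cumsum(c(0, d))
}

#' Rotation matrix about an axis
#'
#' @param axis Numeric 3-vector (need not be unit length).
#' @param angle Rotation angle in radians (right-handed about `axis`).
#' @return A 3 x 3 proper orthogonal matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be nonzero")
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Haar-ish random rotation (QR of a Gaussian matrix, determinant fixed to +1).
random_rotation <- function(seed = NULL) {
  with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
    Q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    Q <- Q %*% diag(d)
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
  })
}

#' Rotate points about a centre
#'
#' Applies a proper orthogonal rotation to a set of points. Pairwise central
#' angles on any sphere centred at `center` are preserved.
#'
#' @param points Length-3 vector or n x 3 matrix (micrometres).
#' @param rotation A 3 x 3 proper orthogonal matrix.
#' @param center Rotation centre (default origin).
#' @return Rotated points, same shape as an n x 3 matrix.
#' @export
rotate_points <- function(points, rotation, center = c(0, 0, 0)) {
  p <- as_points(points)
  if (!is.matrix(rotation) || !all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3 x 3 matrix")
  if (max(abs(crossprod(rotation) - diag(3L))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be proper orthogonal (R'R = I, det = +1)")
  sweep(sweep(p, 2L, center) %*% t(rotation), 2L, center, "+")
}

#' Trajectory of a structure on a sphere
#'
#' Time-stamped positions of one tracked structure (stream centre of mass,
#' defect core, ...) constrained to a vesicle sphere. Positions beyond the
#' on-sphere tolerance are radially projected onto the sphere with a warning
#' (manually clicked positions are never exactly on-sphere).
#'
#' @param times Strictly increasing times in seconds (length >= 1).
#' @param positions n x 3 matrix of Cartesian positions (micrometres).
#' @param geometry A [sphere_geometry()].
#' @param tol_rel Relative on-sphere tolerance (default 1e-6); larger radial
#'   deviations are projected.
#' @return An object of class `trajectory` with elements `times`, `xyz`,
#'   `geometry`.
#' @export
trajectory <- function(times, positions, geometry, tol_rel = 1e-6) {
  g <- assert_geometry(geometry)
  times <- as.numeric(times)
  p <- as_points(positions)
  if (length(times) != nrow(p)) stop("times and positions must have matching length")
  if (length(times) < 1L) stop("a trajectory needs at least one point")
  if (length(times) > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  r <- radial_dist(p, g)
  if (any(r < 1e-9)) stop("positions at the sphere centre cannot be projected")
  off <- abs(r - g$radius) > tol_rel * g$radius
  if (any(off)) {
    warning(sprintf("%d position(s) off sphere by up to %.3g um; radially projected",
                    sum(off), max(abs(r - g$radius))))
    v <- sweep(p[off, , drop = FALSE], 2L, g$center)
    p[off, ] <- sweep(v * (g$radius / r[off]), 2L, g$center, "+")
  }
  structure(list(times = times, xyz = p, geometry = g), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d points over %.4g s on sphere R = %.4g um\n",
              length(x$times), diff(range(x$times)), x$geometry$radius))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  sph <- cart_to_sph(x$xyz, x$geometry, tol_rel = 1e-3)
  data.frame(time_s = x$times, x_um = x$xyz[, 1], y_um = x$xyz[, 2], z_um = x$xyz[, 3],
             theta_rad = sph$theta, phi_rad = sph$phi)
}
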