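# Projections of confocal voxel stacks of spherical vesicles: sphere
# fitting, equirectangular maps, hemisphere and z maximum projections, and
# latitude intensity profiles.

#' Voxel stack container
#'
#' A 3D (x, y, z) fluorescence intensity grid with physical voxel sizes.
#' Index `[i, j, k]` sits at `origin_um + (i-1, j-1, k-1) * voxel_um` in the
#' lab frame (voxel centres).
#'
#' @param intensity 3D numeric array (x, y, z), finite and non-negative
#'   values allowed to be any finite number after noise addition.
#' @param voxel_um Voxel size in micrometres; scalar or length-3 (x, y, z).
#' @param origin_um Lab-frame position of voxel `[1,1,1]`; default centres
#'   the grid on the origin.
#' @param frame_interval_s Optional frame interval when the stack is one
#'   frame of a time series.
#' @return Object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensity, voxel_um, origin_um = NULL, frame_interval_s = NULL) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("intensity must be a 3D array (x, y, z)")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  voxel_um <- as.numeric(voxel_um)
  if (length(voxel_um) == 1L) voxel_um <- rep(voxel_um, 3L)
  if (length(voxel_um) != 3L || any(voxel_um <= 0)) stop("voxel_um must be positive (x, y, z)")
  d <- dim(intensity)
  if (is.null(origin_um)) origin_um <- -(d - 1) / 2 * voxel_um
  structure(list(intensity = intensity, voxel_um = voxel_um,
                 origin_um = as.numeric(origin_um), frame_interval_s = frame_interval_s),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("voxel_stack: %d x %d x %d voxels, voxel (%.3g, %.3g, %.3g) um\n",
              d[1], d[2], d[3], x$voxel_um[1], x$voxel_um[2], x$voxel_um[3]))
  invisible(x)
}

# Trilinear interpolation of stack intensity at lab-frame points (n x 3 um).
# Out-of-bounds points are clamped to the grid; `oob` reports whether any were.
sample_trilinear <- function(stack, pts) {
  A <- stack$intensity
  d <- dim(A)
  f <- sweep(sweep(pts, 2L, stack$origin_um), 2L, stack$voxel_um, "/") + 1
  oob <- any(f < 1 - 1e-9) || any(f > rep(d, each = nrow(f)) + 1e-9)
  f1 <- clamp(f[, 1], 1, d[1]); f2 <- clamp(f[, 2], 1, d[2]); f3 <- clamp(f[, 3], 1, d[3])
  i0 <- pmin(floor(f1), d[1] - 1L); j0 <- pmin(floor(f2), d[2] - 1L); k0 <- pmin(floor(f3), d[3] - 1L)
  wx <- f1 - i0; wy <- f2 - j0; wz <- f3 - k0
  idx <- function(i, j, k) A[cbind(i, j, k)]
  v <- idx(i0, j0, k0) * (1 - wx) * (1 - wy) * (1 - wz) +
    idx(i0 + 1, j0, k0) * wx * (1 - wy) * (1 - wz) +
    idx(i0, j0 + 1, k0) * (1 - wx) * wy * (1 - wz) +
    idx(i0, j0, k0 + 1) * (1 - wx) * (1 - wy) * wz +
    idx(i0 + 1, j0 + 1, k0) * wx * wy * (1 - wz) +
    idx(i0 + 1, j0, k0 + 1) * wx * (1 - wy) * wz +
    idx(i0, j0 + 1, k0 + 1) * (1 - wx) * wy * wz +
    idx(i0 + 1, j0 + 1, k0 + 1) * wx * wy * wz
  list(values = v, oob = oob)
}

#' Fit a sphere to the bright shell of a voxel stack
#'
#' Algebraic least-squares sphere fit (Coope): voxels above an intensity
#' quantile threshold vote with their centre coordinates, and centre and
#' radius minimizing the sum of squared algebraic residuals are obtained from
#' one linear solve. No iterative refinement is applied.
#'
#' @param stack A [voxel_stack()] containing a shell-like intensity
#'   distribution.
#' @param threshold_quantile Quantile of the intensity distribution above
#'   which voxels are used (default 0.99).
#' @return A [sphere_geometry()] with attributes `rms_um` (RMS radial
#'   residual) and `n_points`.
#' @export
fit_sphere <- function(stack, threshold_quantile = 0.99) {
  if (!inherits(stack, "voxel_stack")) stop("stack must be a voxel_stack")
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("threshold_quantile must be in (0, 1)")
  vals <- as.numeric(stack$intensity)
  thr <- stats::quantile(vals, threshold_quantile, names = FALSE)
  sel <- which(vals > thr)
  if (length(sel) < 10L)
    stop("insufficient signal: fewer than 10 voxels above the intensity threshold")
  ijk <- arrayInd(sel, dim(stack$intensity))
  xyz <- sweep(sweep(ijk - 1, 2L, stack$voxel_um, "*"), 2L, stack$origin_um, "+")
  B <- cbind(2 * xyz, 1)
  f <- rowSums(xyz^2)
  beta <- stats::lm.fit(B, f)$coefficients
  center <- beta[1:3]
  R2 <- beta[4] + sum(center^2)
  if (!is.finite(R2) || R2 <= 0) stop("degenerate sphere fit")
  g <- sphere_geometry(sqrt(R2), center)
  res <- radial_dist(xyz, g) - g$radius
  attr(g, "rms_um") <- sqrt(mean(res^2))
  attr(g, "n_points") <- length(sel)
  g
}

#' Equirectangular intensity map
#'
#' Intensity on a (colatitude, azimuth) grid. Row `i` is centred at
#' `theta = (i - 1/2) * pi / n_theta` and column `j` at
#' `phi = (j - 1/2) * 2*pi / n_phi`; rows span `[0, pi]`, columns the
#' half-open `[0, 2*pi)`.
#'
#' @param intensity `n_theta x n_phi` numeric matrix.
#' @param geometry A [sphere_geometry()].
#' @param time_s Optional acquisition time of this map.
#' @return Object of class `equirect_map` (a matrix with metadata).
#' @export
equirect_map <- function(intensity, geometry, time_s = NULL) {
  if (!is.matrix(intensity) || !all(is.finite(intensity)))
    stop("intensity must be a finite numeric matrix")
  g <- assert_geometry(geometry)
  structure(intensity, geometry = g, time_s = time_s, class = c("equirect_map", "matrix"))
}

#' @export
print.equirect_map <- function(x, ...) {
  cat(sprintf("equirect_map: %d (theta) x %d (phi) px on sphere R = %.4g um\n",
              nrow(x), ncol(x), attr(x, "geometry")$radius))
  invisible(x)
}

map_theta_centers <- function(m) ((seq_len(nrow(m)) - 0.5) * pi) / nrow(m)
map_phi_centers <- function(m) ((seq_len(ncol(m)) - 0.5) * 2 * pi) / ncol(m)

#' Time-ordered sequence of equirectangular maps
#'
#' @param maps List of [equirect_map()] objects of identical size.
#' @param times Frame times in seconds (strictly increasing).
#' @return Object of class `equirect_seq`.
#' @export
equirect_seq <- function(maps, times) {
  if (!length(maps)) stop("maps must be nonempty")
  if (length(maps) != length(times)) stop("one time per map required")
  if (length(times) > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  dims <- vapply(maps, dim, integer(2L))
  if (any(dims != dims[, 1L])) stop("all maps must share dimensions")
  structure(list(maps = maps, times = as.numeric(times),
                 geometry = attr(maps[[1L]], "geometry")),
            class = "equirect_seq")
}

#' Equirectangular projection of a voxel stack
#'
#' For every map pixel direction `(theta, phi)` the stack is sampled (with
#' trilinear interpolation) along the radial segment
#' `[R - shell_halfwidth, R + shell_halfwidth]` and reduced by the maximum
#' (default, matching maximum-style fluorescence projections) or the mean.
#' Deterministic for fixed inputs. Samples falling outside the stack are
#' clamped to its bounds with a warning.
#'
#' @param stack A [voxel_stack()].
#' @param geometry A [sphere_geometry()] (typically from [fit_sphere()]).
#' @param shell_halfwidth_um Half-width of the sampled radial shell (um).
#' @param n_theta,n_phi Map resolution; defaults 360 x 720 (about 0.5 degree
#'   bins, i.e. ~0.16 um at the equator of an 18 um vesicle).
#' @param reduce `"max"` or `"mean"` radial reduction.
#' @return An [equirect_map()].
#' @export
project_equirectangular <- function(stack, geometry, shell_halfwidth_um = 1,
                                    n_theta = 360L, n_phi = 720L,
                                    reduce = c("max", "mean")) {
  if (!inherits(stack, "voxel_stack")) stop("stack must be a voxel_stack")
  g <- assert_geometry(geometry)
  reduce <- match.arg(reduce)
  if (shell_halfwidth_um <= 0) stop("shell_halfwidth_um must be positive")
  tc <- ((seq_len(n_theta) - 0.5) * pi) / n_theta
  pc <- ((seq_len(n_phi) - 0.5) * 2 * pi) / n_phi
  th <- rep(tc, times = n_phi)
  ph <- rep(pc, each = n_theta)
  U <- cbind(cos(ph) * sin(th), sin(ph) * sin(th), cos(th))
  n_r <- max(5L, ceiling(2 * shell_halfwidth_um / (min(stack$voxel_um) / 4)) + 1L)
  radii <- seq(g$radius - shell_halfwidth_um, g$radius + shell_halfwidth_um, length.out = n_r)
  acc <- if (reduce == "max") rep(-Inf, nrow(U)) else numeric(nrow(U))
  any_oob <- FALSE
  for (r in radii) {
    pts <- sweep(r * U, 2L, g$center, "+")
    s <- sample_trilinear(stack, pts)
    any_oob <- any_oob || s$oob
    acc <- if (reduce == "max") pmax(acc, s$values) else acc + s$values / n_r
  }
  if (any_oob) warning("radial shell exits stack bounds; samples clamped to the grid")
  equirect_map(matrix(acc, n_theta, n_phi), g)
}

#' Maximum z-projection of a voxel stack
#'
#' @param stack A [voxel_stack()].
#' @return Matrix indexed (x, y): per-(x, y) maximum over z.
#' @export
z_projection <- function(stack) {
  if (!inherits(stack, "voxel_stack")) stop("stack must be a voxel_stack")
  d <- dim(stack$intensity)
  Reduce(pmax, lapply(seq_len(d[3]), function(k) stack$intensity[, , k]))
}

#' Hemisphere maximum projection
#'
#' z-projection restricted to voxels with z at or above (`"top"`) or below
#' (`"bottom"`) the sphere centre plane; used to show the two halves of a
#' fully covered vesicle separately.
#'
#' @param stack A [voxel_stack()].
#' @param geometry A [sphere_geometry()] supplying the centre plane.
#' @param which `"top"` or `"bottom"`.
#' @return Matrix indexed (x, y).
#' @export
hemisphere_projection <- function(stack, geometry, which = c("top", "bottom")) {
  if (!inherits(stack, "voxel_stack")) stop("stack must be a voxel_stack")
  g <- assert_geometry(geometry)
  which <- match.arg(which)
  d <- dim(stack$intensity)
  zc <- stack$origin_um[3] + (seq_len(d[3]) - 1) * stack$voxel_um[3]
  keep <- if (which == "top") zc >= g$center[3] else zc < g$center[3]
  if (!any(keep)) return(matrix(0, d[1], d[2]))
  Reduce(pmax, lapply(which(keep), function(k) stack$intensity[, , k]))
}

#' Latitude intensity profile of an equirectangular map
#'
#' Per-colatitude-row mean intensity, normalized so its trapezoidal integral
#' over theta equals one. By default every (theta, phi) pixel counts equally,
#' matching a profile read directly off an equirectangular image; the
#' `"area"` weighting multiplies rows by sin(theta) for a true per-area
#' density before normalization.
#'
#' @param m An [equirect_map()].
#' @param weight `"pixel"` (default) or `"area"`.
#' @return Data frame of class `latitude_profile` with columns `theta`
#'   (bin centres, radians) and `intensity` (1/radian).
#' @export
latitude_intensity_profile <- function(m, weight = c("pixel", "area")) {
  if (!inherits(m, "equirect_map")) stop("m must be an equirect_map")
  weight <- match.arg(weight)
  th <- map_theta_centers(m)
  f <- rowMeans(unclass(m))
  if (weight == "area") f <- f * sin(th)
  z <- trapz(th, f)
  if (!is.finite(z) || z <= 0)
    stop("degenerate normalization: map has no positive latitude signal")
  structure(data.frame(theta = th, intensity = f / z),
            class = c("latitude_profile", "data.frame"))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Fraction of sphere area above an intensity threshold
#'
#' Solid-angle-weighted coverage of an equirectangular map: the sum of
#' sin(theta) over above-threshold pixels divided by the sum over all pixels.
#' Supports the distinction between patterns covering a fraction of the
#' vesicle surface and those covering the full vesicle.
#'
#' @param m An [equirect_map()].
#' @param threshold Intensity threshold (pixels strictly above count).
#' @return Coverage fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(m, threshold) {
  if (!inherits(m, "equirect_map")) stop("m must be an equirect_map")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single non-negative number")
  w <- sin(map_theta_centers(m))
  W <- matrix(w, nrow(m), ncol(m))
  sum(W[unclass(m) > threshold]) / sum(W)
}
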