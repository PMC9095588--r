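# Seeded kinematic generators and renderers of synthetic vesicle scenes.
#
# The generators are kinematic, not mechanistic: structures move along
# prescribed constant-latitude circles (streams, vortices, bands) or diffuse
# with a prescribed surface diffusion coefficient (jammed defects), at the
# speed scales observed in the experiments (moving structures ~40-50 nm/s,
# jammed defects below ~5 nm/s, vesicle radius ~18 um). Every generator is a
# pure function of its spec and seed.

#' Specification of one synthetic structure
#'
#' @param kind `"stream"` (arc-shaped tube of finite length), `"vortex"`
#'   (closed constant-latitude loop), `"band"` (surface-spanning,
#'   equator-peaked latitudinal intensity profile), or `"jammed_defects"`
#'   (four slow comet-like defects plus dense background).
#' @param theta0 Colatitude of the structure's circle in radians.
#' @param speed_nm_s Arc speed of the structure's centre of mass (nm/s).
#' @param omega_rad_s Optional azimuthal angular rate overriding
#'   `speed_nm_s` (`v = omega * R * sin(theta0)`).
#' @param handedness +1 (increasing azimuth) or -1.
#' @param phi0 Initial azimuth (radians); NULL draws one from the scene seed.
#' @param arc_length_um Arc length of a stream tube.
#' @param tube_width_um Gaussian cross-section width of tubes/blobs.
#' @param band_sd_rad Latitudinal standard deviation of a band profile.
#' @param amplitude Peak rendered intensity.
#' @param charges,target_mean_angle_deg,D_um2_s,background For
#'   `"jammed_defects"`: defect charges, initial mean pair angle target
#'   (109.47 tetrahedral, 120 planar), positional diffusion coefficient
#'   (um^2/s), and background intensity of the jammed filament carpet.
#' @return List of class `structure_spec`.
#' @export
structure_spec <- function(kind = c("stream", "vortex", "band", "jammed_defects"),
                           theta0 = pi / 2, speed_nm_s = 45, omega_rad_s = NULL,
                           handedness = 1, phi0 = NULL,
                           arc_length_um = 15, tube_width_um = 1.5,
                           band_sd_rad = 0.6, amplitude = 1,
                           charges = rep("+1/2", 4L),
                           target_mean_angle_deg = 109.47, D_um2_s = 1e-4,
                           background = 0.35) {
  kind <- match.arg(kind)
  if (speed_nm_s < 0) stop("speed must be non-negative")
  if (D_um2_s < 0) stop("diffusion coefficient must be non-negative")
  if (kind %in% c("stream", "vortex") && sin(theta0) < 1e-9 &&
      (speed_nm_s > 0 || !is.null(omega_rad_s)))
    stop("degenerate circle: theta0 at a pole with nonzero speed")
  structure(list(kind = kind, theta0 = theta0, speed_nm_s = speed_nm_s,
                 omega_rad_s = omega_rad_s, handedness = sign(handedness),
                 phi0 = phi0, arc_length_um = arc_length_um,
                 tube_width_um = tube_width_um, band_sd_rad = band_sd_rad,
                 amplitude = amplitude, charges = charges,
                 target_mean_angle_deg = target_mean_angle_deg,
                 D_um2_s = D_um2_s, background = background),
            class = "structure_spec")
}

#' Specification of a synthetic vesicle movie
#'
#' @param geometry A [sphere_geometry()]; default an 18 um vesicle.
#' @param dt_s Frame interval in seconds (> 0).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; with it set, all outputs are reproducible.
#' @param structures List of [structure_spec()] objects.
#' @param noise List with `intensity_sd` (additive Gaussian rendering noise,
#'   in units of the structure amplitude) and `jitter_sd_rad` (independent
#'   per-frame angular jitter of structure positions).
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(geometry = sphere_geometry(18), dt_s = 60, n_frames = 30L,
                       seed = 1L, structures = list(),
                       noise = list(intensity_sd = 0.05, jitter_sd_rad = 0.002)) {
  assert_geometry(geometry)
  if (dt_s <= 0) stop("dt_s must be positive")
  if (n_frames < 1L) stop("n_frames must be at least 1")
  noise$intensity_sd <- noise$intensity_sd %||% 0
  noise$jitter_sd_rad <- noise$jitter_sd_rad %||% 0
  structure(list(geometry = geometry, dt_s = dt_s, n_frames = as.integer(n_frames),
                 seed = seed, structures = structures, noise = noise),
            class = "scene_spec")
}

scene_times <- function(scene) (seq_len(scene$n_frames) - 1L) * scene$dt_s

#' Sample filament lengths from a mode-parameterized log-normal
#'
#' Filament lengths follow a log-normal distribution whose mode (not mean)
#' is `mode_um`; the log-scale location is therefore
#' `mu = log(mode_um) + sigma_log^2`.
#'
#' @param n Number of samples (>= 1).
#' @param mode_um Distribution mode in micrometres (default 0.6).
#' @param sigma_log Log-scale standard deviation (default 0.5).
#' @param seed Optional seed.
#' @return Numeric vector of lengths in micrometres.
#' @export
sample_filament_lengths <- function(n, mode_um = 0.6, sigma_log = 0.5, seed = NULL) {
  if (n < 1L || mode_um <= 0 || sigma_log <= 0) stop("invalid length-distribution parameters")
  with_seed(seed, stats::rlnorm(n, meanlog = log(mode_um) + sigma_log^2, sdlog = sigma_log))
}

#' Trajectory of a moving synthetic structure
#'
#' Centre-of-mass path along the circle of colatitude `theta0` at azimuthal
#' rate `omega = v / (R sin(theta0))` (or the explicit `omega_rad_s`), plus
#' optional independent per-frame angular jitter from the scene noise model.
#' The noiseless ground-truth speed is recorded as an attribute.
#'
#' @param struct A [structure_spec()] of kind `"stream"`, `"vortex"` or
#'   `"band"`.
#' @param scene A [scene_spec()].
#' @param stream_index Index used to decorrelate seeds between structures.
#' @return A [trajectory()] with attributes `speed_nm_s` (ground truth) and
#'   `omega_rad_s`.
#' @export
make_structure_trajectory <- function(struct, scene, stream_index = 1L) {
  if (!inherits(struct, "structure_spec")) stop("struct must be a structure_spec")
  if (!inherits(scene, "scene_spec")) stop("scene must be a scene_spec")
  if (struct$kind == "jammed_defects") stop("use make_jammed_scene for jammed defects")
  g <- scene$geometry
  if (sin(struct$theta0) < 1e-9 && (struct$speed_nm_s > 0 || !is.null(struct$omega_rad_s)))
    stop("degenerate circle: theta0 at a pole with nonzero speed")
  omega <- struct$omega_rad_s %||% (struct$speed_nm_s * 1e-3 / (g$radius * sin(struct$theta0)))
  times <- scene_times(scene)
  phi0 <- struct$phi0 %||% with_seed(sub_seed(scene$seed, 100L + stream_index),
                                     stats::runif(1, 0, 2 * pi))
  phi <- phi0 + struct$handedness * omega * times
  theta <- rep(struct$theta0, length(times))
  jsd <- scene$noise$jitter_sd_rad
  if (jsd > 0) {
    jit <- with_seed(sub_seed(scene$seed, 200L + stream_index),
                     matrix(stats::rnorm(2L * length(times), sd = jsd), ncol = 2L))
    theta <- clamp(theta + jit[, 1L], 1e-6, pi - 1e-6)
    phi <- phi + jit[, 2L]
  }
  tr <- trajectory(times, sph_to_cart(theta, phi %% (2 * pi), g), g)
  attr(tr, "speed_nm_s") <- abs(omega) * g$radius * sin(struct$theta0) * 1000
  attr(tr, "omega_rad_s") <- omega
  tr
}

# Colatitude beta of the disphenoid family interpolating tetrahedral
# (beta = acos(1/sqrt(3))) and planar square (beta = pi/2) four-point
# configurations: two points at (beta; phi = 0, pi), two at (pi - beta;
# phi = pi/2, 3pi/2). Mean pair angle is monotone in beta on this family.
disphenoid_unit_vectors <- function(beta) {
  rbind(c(sin(beta), 0, cos(beta)),
        c(-sin(beta), 0, cos(beta)),
        c(0, sin(pi - beta), cos(pi - beta)),
        c(0, -sin(pi - beta), cos(pi - beta)))
}

disphenoid_mean_angle <- function(beta) {
  u <- disphenoid_unit_vectors(beta)
  idx <- utils::combn(4L, 2L)
  d <- vapply(seq_len(ncol(idx)), function(k) sum(u[idx[1L, k], ] * u[idx[2L, k], ]),
              numeric(1L))
  mean(acos(clamp(d, -1, 1))) * 180 / pi
}

solve_disphenoid_beta <- function(target_deg) {
  lo <- acos(1 / sqrt(3)); hi <- pi / 2
  f <- function(b) disphenoid_mean_angle(b) - target_deg
  if (target_deg <= disphenoid_mean_angle(lo) + 1e-9) return(lo)
  if (target_deg >= disphenoid_mean_angle(hi) - 1e-9) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Generate a jammed four-defect scene
#'
#' Four defects start in a configuration whose mean pair angle equals the
#' target (tetrahedral 109.47 degrees by default; 120 gives the planar
#' square; intermediate targets use the interpolating disphenoid family),
#' randomly oriented by a seeded rotation, and subsequently perform surface
#' diffusion: isotropic tangent-plane Gaussian steps of per-component
#' variance `2 * D * dt` (total squared step `4 D dt`), radially re-projected
#' onto the sphere.
#'
#' @param scene A [scene_spec()]; its `dt_s`, `n_frames` and `seed` drive
#'   the dynamics.
#' @param charges Four charges; four +1/2 sum to the +2 a fully covered
#'   sphere requires. Other sums are generated but flagged by
#'   [validate_poincare_hopf()].
#' @param target_mean_angle_deg Initial mean pair angle target in degrees.
#' @param D_um2_s Surface diffusion coefficient (um^2/s).
#' @param covers_full_surface Flag carried into the per-frame
#'   configurations.
#' @return List of class `jammed_scene`: `trajectories` (four
#'   [trajectory()]s), `configurations` (per-frame
#'   [defect_configuration()]s), `series` (a [configuration_series()]),
#'   `charges`.
#' @export
make_jammed_scene <- function(scene = scene_spec(), charges = rep("+1/2", 4L),
                              target_mean_angle_deg = 109.47, D_um2_s = 1e-4,
                              covers_full_surface = TRUE) {
  if (!inherits(scene, "scene_spec")) stop("scene must be a scene_spec")
  half <- parse_charge(charges)
  if (length(half) != 4L) stop("a jammed scene has exactly four defects")
  g <- scene$geometry
  beta <- solve_disphenoid_beta(target_mean_angle_deg)
  u0 <- disphenoid_unit_vectors(beta)
  rot <- random_rotation(sub_seed(scene$seed, 300L))
  u0 <- u0 %*% t(rot)
  times <- scene_times(scene)
  n <- length(times)
  pos <- array(NA_real_, c(n, 4L, 3L))
  pos[1L, , ] <- u0 * g$radius
  step_sd <- sqrt(2 * D_um2_s * scene$dt_s)
  if (n > 1L) {
    steps <- with_seed(sub_seed(scene$seed, 301L),
                       array(stats::rnorm(2L * 4L * (n - 1L), sd = step_sd),
                             c(n - 1L, 4L, 2L)))
    for (i in 2L:n) {
      for (d in 1L:4L) {
        p <- pos[i - 1L, d, ]
        r <- sqrt(sum(p^2))
        u <- p / r
        # orthonormal tangent basis at u
        a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(u[2] * e1[3] - u[3] * e1[2],
                u[3] * e1[1] - u[1] * e1[3],
                u[1] * e1[2] - u[2] * e1[1])
        q <- p + steps[i - 1L, d, 1L] * e1 + steps[i - 1L, d, 2L] * e2
        pos[i, d, ] <- q / sqrt(sum(q^2)) * g$radius
      }
    }
  }
  trajs <- lapply(1L:4L, function(d)
    trajectory(times, sweep(matrix(pos[, d, ], ncol = 3L), 2L, g$center, "+"), g))
  configs <- lapply(seq_len(n), function(i)
    defect_configuration(charges, g,
                         xyz = sweep(matrix(pos[i, , ], 4L, 3L), 2L, g$center, "+"),
                         time_s = times[i], covers_full_surface = covers_full_surface))
  series <- configuration_series(trajs, charges, covers_full_surface)
  structure(list(trajectories = trajs, configurations = configs, series = series,
                 charges = charges),
            class = "jammed_scene")
}

#' Seeded angular random walk on the sphere
#'
#' Independent Gaussian increments of given standard deviation per frame in
#' both angular coordinates (colatitude reflected at the poles), providing a
#' diffusive reference trajectory for MSD scaling checks.
#'
#' @param n_frames Number of frames.
#' @param dt_s Frame interval (s).
#' @param step_sd_rad Per-frame, per-component angular step SD (radians).
#' @param theta0 Starting colatitude.
#' @param geometry A [sphere_geometry()].
#' @param seed Optional seed.
#' @return A [trajectory()].
#' @export
make_angular_random_walk <- function(n_frames, dt_s, step_sd_rad,
                                     theta0 = pi / 2,
                                     geometry = sphere_geometry(18), seed = NULL) {
  g <- assert_geometry(geometry)
  steps <- with_seed(seed, matrix(stats::rnorm(2L * (n_frames - 1L), sd = step_sd_rad),
                                  ncol = 2L))
  theta <- theta0 + c(0, cumsum(steps[, 1L]))
  # reflect colatitude into (0, pi)
  theta <- abs(theta) %% (2 * pi)
  theta <- ifelse(theta > pi, 2 * pi - theta, theta)
  theta <- clamp(theta, 1e-6, pi - 1e-6)
  phi <- c(0, cumsum(steps[, 2L])) %% (2 * pi)
  times <- (seq_len(n_frames) - 1L) * dt_s
  trajectory(times, sph_to_cart(theta, phi, g), g)
}

# ---- renderers --------------------------------------------------------------

# Angular intensity of all scene structures evaluated at unit directions U
# (n x 3, relative to the sphere centre) at a given frame. `realized` is the
# output of realize_scene().
scene_angular_intensity <- function(scene, realized, frame, U) {
  total <- numeric(nrow(U))
  R <- scene$geometry$radius
  for (i in seq_along(scene$structures)) {
    s <- scene$structures[[i]]
    if (s$kind == "band") {
      theta <- acos(clamp(U[, 3L], -1, 1))
      total <- total + s$amplitude * exp(-(theta - s$theta0)^2 / (2 * s$band_sd_rad^2))
      next
    }
    if (s$kind == "jammed_defects") {
      jam <- realized$jammed[[as.character(i)]]
      xyz <- do.call(rbind, lapply(jam$trajectories, function(tr) tr$xyz[frame, ]))
      C <- sweep(xyz, 2L, scene$geometry$center) / R
      dot <- U %*% t(C)
      d2 <- 2 * R^2 * pmax(1 - apply(dot, 1L, max), 0)
      total <- total + s$background + s$amplitude * exp(-d2 / (2 * s$tube_width_um^2))
      next
    }
    tr <- realized$trajs[[as.character(i)]]
    com <- tr$xyz[frame, ] - scene$geometry$center
    com_sph <- cart_to_sph(matrix(com + scene$geometry$center, 1L), scene$geometry,
                           tol_rel = 1e-3)
    half_arc <- if (s$kind == "vortex") pi else
      (s$arc_length_um / 2) / (R * sin(s$theta0))
    n_samp <- max(15L, ceiling(2 * half_arc * R * sin(s$theta0) / (s$tube_width_um / 2)))
    dphi <- seq(-half_arc, half_arc, length.out = n_samp)
    if (s$kind == "vortex") dphi <- dphi[-n_samp]  # closed loop, avoid duplicate
    cs <- sph_to_cart(rep(com_sph$theta, length(dphi)),
                      (com_sph$phi + dphi) %% (2 * pi), scene$geometry)
    C <- sweep(cs, 2L, scene$geometry$center) / R
    # chunk the pixel-by-sample dot products to bound memory
    best <- rep(-1, nrow(U))
    chunk <- 60000L
    for (a in seq(1L, nrow(U), by = chunk)) {
      b <- min(a + chunk - 1L, nrow(U))
      dot <- U[a:b, , drop = FALSE] %*% t(C)
      best[a:b] <- do.call(pmax, as.data.frame(dot))
    }
    d2 <- 2 * R^2 * pmax(1 - best, 0)
    total <- total + s$amplitude * exp(-d2 / (2 * s$tube_width_um^2))
  }
  total
}

# Realize the stochastic parts of a scene once (pure function of the spec).
realize_scene <- function(scene) {
  trajs <- list(); jammed <- list()
  for (i in seq_along(scene$structures)) {
    s <- scene$structures[[i]]
    if (s$kind == "jammed_defects") {
      jammed[[as.character(i)]] <- make_jammed_scene(scene, s$charges,
                                                     s$target_mean_angle_deg, s$D_um2_s)
    } else {
      trajs[[as.character(i)]] <- make_structure_trajectory(s, scene, stream_index = i)
    }
  }
  list(trajs = trajs, jammed = jammed)
}

#' Render one equirectangular frame of a synthetic scene
#'
#' Each structure is drawn with a Gaussian cross-section around its 3D curve
#' on the sphere, the intensity at a map pixel obtained by evaluating the 3D
#' tube profile in the pixel's direction (so no equirectangular area
#' distortion is introduced), plus seeded additive Gaussian noise.
#' Deterministic for a fixed scene spec.
#'
#' @param scene A [scene_spec()].
#' @param frame Frame index (1-based).
#' @param n_theta,n_phi Map resolution.
#' @param realized Internal cache from a previous call (optional).
#' @return An [equirect_map()].
#' @export
render_equirect <- function(scene, frame, n_theta = 180L, n_phi = 360L,
                            realized = NULL) {
  if (!inherits(scene, "scene_spec")) stop("scene must be a scene_spec")
  if (frame < 1L || frame > scene$n_frames) stop("frame out of range")
  realized <- realized %||% realize_scene(scene)
  tc <- ((seq_len(n_theta) - 0.5) * pi) / n_theta
  pc <- ((seq_len(n_phi) - 0.5) * 2 * pi) / n_phi
  th <- rep(tc, times = n_phi); ph <- rep(pc, each = n_theta)
  U <- cbind(cos(ph) * sin(th), sin(ph) * sin(th), cos(th))
  v <- scene_angular_intensity(scene, realized, frame, U)
  if (scene$noise$intensity_sd > 0) {
    v <- v + with_seed(sub_seed(scene$seed, 400L + frame),
                       stats::rnorm(length(v), sd = scene$noise$intensity_sd))
  }
  equirect_map(matrix(v, n_theta, n_phi), scene$geometry,
               time_s = (frame - 1L) * scene$dt_s)
}

#' Render all frames of a scene as an equirectangular sequence
#'
#' @param scene A [scene_spec()].
#' @param n_theta,n_phi Map resolution.
#' @param frames Frame indices to render (default all).
#' @return An [equirect_seq()].
#' @export
render_scene <- function(scene, n_theta = 180L, n_phi = 360L, frames = NULL) {
  frames <- frames %||% seq_len(scene$n_frames)
  realized <- realize_scene(scene)
  maps <- lapply(frames, function(f) render_equirect(scene, f, n_theta, n_phi, realized))
  equirect_seq(maps, (frames - 1L) * scene$dt_s)
}

#' Render a voxel stack of a synthetic vesicle
#'
#' A voxelized spherical shell (Gaussian or flat-top radial profile)
#' modulated by the scene's angular structure intensities, plus seeded
#' Gaussian background noise. The flat-top profile emulates a uniformly
#' fluorescent membrane of finite thickness; the Gaussian profile a
#' diffraction-blurred one.
#'
#' @param scene A [scene_spec()].
#' @param frame Frame index.
#' @param voxel_um Isotropic voxel size (um).
#' @param shell_profile `"gaussian"` or `"flat"`.
#' @param shell_sigma_um Gaussian radial sigma (um).
#' @param shell_thickness_um Full thickness of the flat-top shell (um).
#' @param shell_amplitude Intensity of the bare membrane shell.
#' @param extent_um Optional half-extent of the cubic grid from the sphere
#'   centre; must contain the shell, else an error is signalled. Default
#'   auto-sizes to the sphere plus shell.
#' @param noise_sd Additive Gaussian noise SD; defaults to the scene's
#'   intensity noise.
#' @return A [voxel_stack()].
#' @export
render_stack <- function(scene, frame = 1L, voxel_um = 0.5,
                         shell_profile = c("gaussian", "flat"),
                         shell_sigma_um = 1, shell_thickness_um = 2,
                         shell_amplitude = 1, extent_um = NULL, noise_sd = NULL) {
  if (!inherits(scene, "scene_spec")) stop("scene must be a scene_spec")
  shell_profile <- match.arg(shell_profile)
  g <- scene$geometry
  pad <- if (shell_profile == "gaussian") 3 * shell_sigma_um else shell_thickness_um / 2
  need <- g$radius + pad + voxel_um
  if (is.null(extent_um)) extent_um <- need
  if (extent_um < need)
    stop(sprintf("scene larger than requested stack bounds (need half-extent >= %.3g um)", need))
  nside <- 2L * ceiling(extent_um / voxel_um) + 1L
  org <- g$center - (nside - 1) / 2 * voxel_um
  ax <- org[1] + (seq_len(nside) - 1) * voxel_um
  ay <- org[2] + (seq_len(nside) - 1) * voxel_um
  az <- org[3] + (seq_len(nside) - 1) * voxel_um
  X <- rep(ax, times = nside * nside) - g$center[1]
  Y <- rep(rep(ay, each = nside), times = nside) - g$center[2]
  Z <- rep(az, each = nside * nside) - g$center[3]
  r <- sqrt(X^2 + Y^2 + Z^2)
  radial <- if (shell_profile == "gaussian") {
    exp(-(r - g$radius)^2 / (2 * shell_sigma_um^2))
  } else {
    as.numeric(abs(r - g$radius) <= shell_thickness_um / 2)
  }
  vals <- numeric(length(r))
  sel <- which(radial > 1e-4 & r > 1e-9)
  if (length(sel)) {
    ang <- if (length(scene$structures)) {
      U <- cbind(X[sel], Y[sel], Z[sel]) / r[sel]
      scene_angular_intensity(scene, realize_scene(scene), frame, U)
    } else 0
    vals[sel] <- radial[sel] * (shell_amplitude + ang)
  }
  noise_sd <- noise_sd %||% scene$noise$intensity_sd
  if (noise_sd > 0) {
    vals <- vals + with_seed(sub_seed(scene$seed, 500L + frame),
                             stats::rnorm(length(vals), sd = noise_sd))
  }
  voxel_stack(array(vals, c(nside, nside, nside)), voxel_um, origin_um = org,
              frame_interval_s = scene$dt_s)
}

# ---- fixture suite ----------------------------------------------------------

fixture_specs <- function() {
  list(
    stream = list(label = "stream", structures = list(
      structure_spec("stream", theta0 = 5 * pi / 12, speed_nm_s = 46,
                     arc_length_um = 15, tube_width_um = 1.5))),
    vortex = list(label = "vortex", structures = list(
      structure_spec("vortex", theta0 = pi / 3, speed_nm_s = 45, tube_width_um = 1.5))),
    double_vortex = list(label = "vortex", structures = list(
      structure_spec("vortex", theta0 = 5 * pi / 18, speed_nm_s = 45, handedness = 1),
      structure_spec("vortex", theta0 = 7 * pi / 18, speed_nm_s = 45, handedness = -1))),
    band = list(label = "band", structures = list(
      structure_spec("band", theta0 = pi / 2, speed_nm_s = 40, band_sd_rad = 0.6))),
    jammed = list(label = "globally_jammed", structures = list(
      structure_spec("jammed_defects", tube_width_um = 2.5, D_um2_s = 1e-4,
                     background = 0.35))))
}

#' Ground-truth-labelled fixture suite of the five pattern classes
#'
#' Builds one seeded scene per pattern kind: a stream (46 nm/s, partial
#' coverage), a vortex (45 nm/s at colatitude 60 degrees), a double vortex
#' (concentric loops of opposite handedness), an equator-peaked band
#' (40 nm/s with two +1 pole defects) and a globally jammed state (four
#' +1/2 defects near the tetrahedral configuration, D = 1e-4 um^2/s).
#'
#' @param seed Base seed; each fixture derives its own sub-seed.
#' @param n_frames Frames per scene.
#' @param dt_s Frame interval (s).
#' @param render Render equirectangular map sequences?
#' @param n_theta,n_phi Map resolution when rendering.
#' @return Named list of fixtures; each has `kind`, `label`, `scene`,
#'   `trajectories` (ground-truth structure tracks), `defects`
#'   (representative [defect_configuration()] or NULL), `defect_tracks`
#'   (jammed scenes), and `maps` (when rendered).
#' @export
fixture_suite <- function(seed = 1L, n_frames = 6L, dt_s = 60, render = TRUE,
                          n_theta = 90L, n_phi = 180L) {
  specs <- fixture_specs()
  out <- list()
  for (k in seq_along(specs)) {
    kind <- names(specs)[k]
    sc <- scene_spec(n_frames = n_frames, dt_s = dt_s,
                     seed = sub_seed(seed, 10L * k),
                     structures = specs[[k]]$structures)
    realized <- realize_scene(sc)
    trajs <- unname(realized$trajs)
    defects <- NULL; defect_tracks <- NULL
    if (kind == "band") {
      defects <- defect_configuration(c("+1", "+1"), sc$geometry,
                                      theta = c(0, pi), phi = c(0, 0),
                                      covers_full_surface = TRUE)
    }
    if (kind == "jammed") {
      jam <- realized$jammed[[1L]]
      defects <- jam$configurations[[1L]]
      defect_tracks <- jam$trajectories
    }
    maps <- if (render) {
      equirect_seq(lapply(seq_len(n_frames), function(f)
        render_equirect(sc, f, n_theta, n_phi, realized)), scene_times(sc))
    } else NULL
    out[[kind]] <- list(kind = kind, label = specs[[k]]$label, scene = sc,
                        trajectories = trajs, defects = defects,
                        defect_tracks = defect_tracks, maps = maps)
  }
  out
}
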