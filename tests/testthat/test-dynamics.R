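test_that("track ingestion re-projects planar positions onto the sphere", {
  g <- sphere_geometry(18)
  rows <- data.frame(time_s = c(0, 60, 120), theta_rad = pi / 2,
                     phi_rad = c(0, 0.1, 0.2))
  tr <- ingest_track(rows, "equirect", g)
  expect_s3_class(tr, "trajectory")
  expect_equal(tr$xyz[, 3], rep(0, 3))
  expect_equal(sqrt(rowSums(tr$xyz^2)), rep(18, 3), tolerance = 1e-12)
  # confocal centre point is the pole
  rc <- data.frame(time_s = c(0, 60), x_um = 0, y_um = 0, hemisphere = "upper")
  trc <- ingest_track(rc, "confocal", g)
  expect_equal(trc$xyz, rbind(c(0, 0, 18), c(0, 0, 18)), ignore_attr = TRUE)
  # confocal point outside the disk names the offending row
  bad <- data.frame(time_s = c(0, 60), x_um = c(0, 13), y_um = c(0, 13),
                    hemisphere = "upper")
  expect_error(ingest_track(bad, "confocal", g), "row")
  # generator track round-trips through its exported table
  sc <- scene_spec(dt_s = 30, n_frames = 20, seed = 4, noise = noiseless)
  tr0 <- make_structure_trajectory(structure_spec("stream", theta0 = 1.1,
                                                  speed_nm_s = 46), sc)
  df <- as.data.frame(tr0)
  tr1 <- ingest_track(data.frame(time_s = df$time_s, theta_rad = df$theta_rad,
                                 phi_rad = df$phi_rad), "equirect", sc$geometry)
  expect_lt(max(abs(tr1$xyz - tr0$xyz)), 1e-6)
})

test_that("instantaneous speeds follow the arc-length formula", {
  g <- sphere_geometry(18)
  static <- trajectory(c(0, 10, 20), matrix(rep(c(18, 0, 0), 3), 3, byrow = TRUE), g)
  expect_equal(instantaneous_speeds(static)$speed_nm_s, c(0, 0))
  quarter <- trajectory(c(0, 60), rbind(c(18, 0, 0), c(0, 18, 0)), g)
  expect_equal(instantaneous_speeds(quarter)$speed_nm_s, 1000 * 18 * (pi / 2) / 60,
               tolerance = 1e-9)
  irregular <- trajectory(c(0, 10, 40), 18 * runif_sphere(3), g)
  expect_error(instantaneous_speeds(irregular), "regular")
})

test_that("a 60-degree-colatitude circle at rate 2.8868e-3 rad/s moves at 45 nm/s", {
  sc <- scene_spec(dt_s = 10, n_frames = 180, seed = 1, noise = noiseless)
  tr <- make_structure_trajectory(structure_spec("stream", theta0 = pi / 3,
                                                 omega_rad_s = 2.8868e-3), sc)
  v <- mean_speed(instantaneous_speeds(tr))
  expect_equal(unname(v["mean"]), 45, tolerance = 0.01)
})

test_that("mean speed reports mean and dispersion over optional windows", {
  expect_equal(mean_speed(rep(46, 10)), c(mean = 46, sd = 0))
  alt <- rep(c(40, 50), 500)
  m <- mean_speed(alt)
  expect_equal(unname(m["mean"]), 45)
  expect_equal(unname(m["sd"]), 5, tolerance = 0.01)
  s <- data.frame(time_s = 1:10, speed_nm_s = 1:10)
  class(s) <- c("speed_series", "data.frame")
  expect_equal(unname(mean_speed(s, window = c(3, 5))["mean"]), 4)
  expect_error(mean_speed(s, window = c(100, 200)), "empty")
})

test_that("angular MSD matches closed forms for rotation and rest", {
  g <- sphere_geometry(18)
  # uniform azimuthal rotation at fixed colatitude: msd_phi = (omega tau)^2,
  # msd_theta = 0, before saturation
  omega <- 1e-3; dt <- 10; n <- 100
  t <- (seq_len(n) - 1) * dt
  tr <- trajectory(t, sph_to_cart(rep(1.0, n), (omega * t) %% (2 * pi), g), g)
  m <- angular_msd(tr, max_lag_frames = 50)
  pos <- m$lag_s > 0
  expect_equal(m$msd_phi[pos], (omega * m$lag_s[pos])^2, tolerance = 1e-9)
  expect_lt(max(m$msd_theta), 1e-18)
  expect_equal(m$msd_phi[1], 0)
  # static trajectory
  trs <- trajectory(t, matrix(rep(c(0, 18, 0), n), n, byrow = TRUE), g)
  ms <- angular_msd(trs, max_lag_frames = 10)
  expect_true(all(ms$msd_theta == 0) && all(ms$msd_phi == 0))
  expect_error(angular_msd(trajectory(c(0, 1, 5), 18 * runif_sphere(3), g)),
               "irregular|uniform")
})

test_that("angular random walks have diffusive MSD within Monte-Carlo error", {
  sigma <- 0.01; dt <- 10; n <- 200; n_walks <- 30
  lags <- 1:5
  per_walk <- sapply(1:n_walks, function(s) {
    tr <- make_angular_random_walk(n, dt, sigma, seed = s)
    angular_msd(tr, max_lag_frames = max(lags))$msd_phi[lags + 1]
  })
  m <- rowMeans(per_walk)
  se <- apply(per_walk, 1, stats::sd) / sqrt(n_walks)
  expect_true(all(abs(m - lags * sigma^2) <= 3 * se))
})

test_that("MSD scaling exponents separate ballistic, diffusive and saturated regimes", {
  sc <- scene_spec(dt_s = 10, n_frames = 200, seed = 2, noise = noiseless)
  tr <- make_structure_trajectory(structure_spec("stream", theta0 = pi / 2,
                                                 omega_rad_s = 1e-3), sc)
  m <- angular_msd(tr)
  expect_equal(as.numeric(msd_scaling_exponent(m, "phi")), 2, tolerance = 0.01)
  # static -> zero MSD, log slope undefined
  g <- sphere_geometry(18)
  trs <- trajectory((0:9) * 10, matrix(rep(c(18, 0, 0), 10), 10, byrow = TRUE), g)
  expect_error(msd_scaling_exponent(angular_msd(trs), "phi"), "zero MSD")
  # beyond the half-period the bounded increment saturates: exponent < 1
  scf <- scene_spec(dt_s = 5, n_frames = 400, seed = 3, noise = noiseless)
  trf <- make_structure_trajectory(structure_spec("stream", theta0 = pi / 2,
                                                  omega_rad_s = 0.02), scf)
  mf <- angular_msd(trf)
  half_period <- pi / 0.02
  expt <- msd_scaling_exponent(mf, "phi", lag_range = c(1.05, 1.9) * half_period)
  expect_lt(as.numeric(expt), 1)
  expect_lte(max(mf$msd_phi), pi^2)
})

test_that("angular MSD is invariant under z-rotation and time reversal", {
  sc <- scene_spec(dt_s = 20, n_frames = 60, seed = 6,
                   noise = list(intensity_sd = 0, jitter_sd_rad = 0.01))
  tr <- make_structure_trajectory(structure_spec("stream", theta0 = 1.2,
                                                 speed_nm_s = 46), sc)
  m0 <- angular_msd(tr, max_lag_frames = 20)
  rot <- rotation_matrix(c(0, 0, 1), 1.234)
  trR <- trajectory(tr$times, rotate_points(tr$xyz, rot), tr$geometry)
  mR <- angular_msd(trR, max_lag_frames = 20)
  expect_equal(mR$msd_phi, m0$msd_phi, tolerance = 1e-9)
  expect_equal(mR$msd_theta, m0$msd_theta, tolerance = 1e-9)
  trT <- trajectory(tr$times, tr$xyz[rev(seq_along(tr$times)), ], tr$geometry)
  mT <- angular_msd(trT, max_lag_frames = 20)
  expect_equal(mT$msd_phi, m0$msd_phi, tolerance = 1e-12)
  expect_equal(mT$msd_theta, m0$msd_theta, tolerance = 1e-12)
})

test_that("feature tracker follows blobs, wraps the azimuth seam, counts tracks", {
  maps <- blob_maps(6, col0 = 30, step_px = 3)
  trks <- track_features(maps, patch_size = 11, search_radius = 6)
  expect_length(trks, 1)
  d <- diff(trks[[1]]$col)
  expect_true(all(abs(d - 3) <= 0.5))
  # seam crossing: unwrapped motion, no jump above pi
  maps2 <- blob_maps(8, col0 = 112, step_px = 3)
  trks2 <- track_features(maps2, patch_size = 11, search_radius = 6)
  expect_length(trks2, 1)
  expect_equal(nrow(trks2[[1]]), 8)
  dphi <- diff(unwrap_azimuth(trks2[[1]]$phi_rad))
  expect_true(all(abs(dphi) < pi))
  expect_true(all(abs(dphi - 3 * 2 * pi / 120) < 2 * pi / 120))
  # two well-separated blobs -> exactly two tracks
  m2 <- lapply(seq_len(4), function(f) {
    a <- unclass(blob_maps(4, col0 = 20, step_px = 2)$maps[[f]])
    b <- unclass(blob_maps(4, col0 = 80, step_px = 2)$maps[[f]])
    equirect_map(a + b, sphere_geometry(18))
  })
  trks3 <- track_features(equirect_seq(m2, (0:3) * 60), patch_size = 11, search_radius = 5)
  expect_length(trks3, 2)
  # featureless frames -> empty set, not an error
  blank <- equirect_seq(lapply(1:2, function(i)
    equirect_map(matrix(0, 40, 80), sphere_geometry(18))), c(0, 60))
  expect_length(track_features(blank, min_response = 0.5), 0)
})

test_that("time-averaged flow recovers direction and magnitude of circulation", {
  g <- sphere_geometry(18)
  n <- 20; dt <- 60; omega <- 45e-3 / 18
  t <- (seq_len(n) - 1) * dt
  track <- data.frame(time_s = t, theta_rad = pi / 2, phi_rad = (omega * t) %% (2 * pi))
  maps <- blob_maps(2, n_theta = 30, n_phi = 60)
  fl <- time_averaged_flow(maps, list(track), g)
  expect_equal(flow_mean_speed(fl), 45, tolerance = 0.01)
  expect_true(all(abs(fl$flow$v_theta_nm_s) < 1e-9))
  expect_true(all(fl$flow$v_phi_nm_s > 0))
  # static track -> zero field
  st <- data.frame(time_s = t, theta_rad = 1, phi_rad = 1)
  fl0 <- time_averaged_flow(maps, list(st), g)
  expect_equal(flow_mean_speed(fl0), 0)
  # counter-rotating vortices: opposite azimuthal velocities in their bands
  t2 <- data.frame(time_s = t, theta_rad = pi / 3, phi_rad = (omega * t) %% (2 * pi))
  t3 <- data.frame(time_s = t, theta_rad = 2 * pi / 3, phi_rad = (-omega * t) %% (2 * pi))
  fl2 <- time_averaged_flow(maps, list(t2, t3), g, n_theta_cells = 2)
  top <- fl2$flow[fl2$flow$theta_rad < pi / 2, ]
  bot <- fl2$flow[fl2$flow$theta_rad > pi / 2, ]
  expect_true(all(top$v_phi_nm_s > 0))
  expect_true(all(bot$v_phi_nm_s < 0))
})
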