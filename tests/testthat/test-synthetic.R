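test_that("filament lengths are log-normal with the requested mode", {
  x <- sample_filament_lengths(1e5, mode_um = 0.6, sigma_log = 0.5, seed = 1)
  expect_true(all(x > 0))
  # histogram mode of the Monte-Carlo sample near the closed-form mode
  h <- hist(x[x < 3], breaks = seq(0, 3, by = 0.05), plot = FALSE)
  expect_true(h$mids[which.max(h$counts)] >= 0.55 && h$mids[which.max(h$counts)] <= 0.65)
  # seeded reproducibility
  expect_identical(x, sample_filament_lengths(1e5, 0.6, 0.5, seed = 1))
  expect_error(sample_filament_lengths(0, 0.6, 0.5), "invalid")
})

test_that("structure trajectories circulate at the prescribed rate", {
  sc <- scene_spec(dt_s = 60, n_frames = 20, seed = 1, noise = noiseless)
  tr <- make_structure_trajectory(structure_spec("stream", theta0 = pi / 2,
                                                 speed_nm_s = 45), sc)
  expect_equal(attr(tr, "omega_rad_s"), 2.5e-3, tolerance = 1e-12)
  v0 <- make_structure_trajectory(structure_spec("stream", theta0 = 1,
                                                 speed_nm_s = 0), sc)
  expect_equal(instantaneous_speeds(v0)$speed_nm_s, rep(0, 19))
  expect_error(make_structure_trajectory(structure_spec("stream", theta0 = 1e-12,
                                                        speed_nm_s = 45), sc),
               "degenerate")
  # noiseless pipeline identity: generator speed recovered within 0.1%
  tr46 <- make_structure_trajectory(structure_spec("vortex", theta0 = 1.1,
                                                   speed_nm_s = 46), sc)
  expect_equal(unname(mean_speed(instantaneous_speeds(tr46))["mean"]), 46,
               tolerance = 1e-3)
})

test_that("speed recovery holds under the default noise model", {
  sc <- scene_spec(dt_s = 60, n_frames = 30, seed = 9)  # default noise
  tr <- make_structure_trajectory(structure_spec("stream", theta0 = 1.2,
                                                 speed_nm_s = 46), sc)
  v <- unname(mean_speed(instantaneous_speeds(tr))["mean"])
  expect_equal(v, 46, tolerance = 0.1)  # within 10% with angular jitter
})

test_that("jammed scenes start at the target configuration and diffuse slowly", {
  sc0 <- scene_spec(dt_s = 60, n_frames = 10, seed = 4, noise = noiseless)
  frozen <- make_jammed_scene(sc0, D_um2_s = 0)
  expect_true(all(sapply(frozen$trajectories, function(t)
    max(instantaneous_speeds(t)$speed_nm_s) == 0)))
  expect_equal(attr(frozen$series, "sd_deg"), 0, tolerance = 1e-12)
  expect_equal(round(mean_pair_angle(frozen$configurations[[1]]), 1), 109.5)
  planar <- make_jammed_scene(sc0, target_mean_angle_deg = 120, D_um2_s = 0)
  expect_equal(mean_pair_angle(planar$configurations[[1]]), 120, tolerance = 1e-6)
  mid <- make_jammed_scene(sc0, target_mean_angle_deg = 115, D_um2_s = 0)
  expect_equal(mean_pair_angle(mid$configurations[[1]]), 115, tolerance = 1e-6)
  # default diffusion: speeds at the few-nm/s scale
  sc <- scene_spec(dt_s = 60, n_frames = 30, seed = 4, noise = noiseless)
  jam <- make_jammed_scene(sc)
  v <- unlist(lapply(jam$trajectories, function(t) instantaneous_speeds(t)$speed_nm_s))
  expect_lte(mean(v), 5)
  expect_gt(mean(v), 0.5)
  # non-neutral charge sets are generated but flagged
  odd <- make_jammed_scene(sc0, charges = c("+1/2", "+1/2", "+1/2", "-1/2"))
  expect_false(validate_poincare_hopf(odd$configurations[[1]])$pass)
})

test_that("the equirect renderer places structures and is seed-deterministic", {
  sc <- scene_spec(seed = 5, n_frames = 2, noise = noiseless, structures = list(
    structure_spec("stream", theta0 = 1.4, phi0 = 2, speed_nm_s = 0,
                   arc_length_um = 0.5, tube_width_um = 1)))
  m <- render_equirect(sc, 1, n_theta = 90, n_phi = 180)
  peak <- which(unclass(m) == max(m), arr.ind = TRUE)
  expect_equal(unname((peak[1, 1] - 0.5) * pi / 90), 1.4, tolerance = 0.04)
  expect_equal(unname((peak[1, 2] - 0.5) * 2 * pi / 180), 2, tolerance = 0.04)
  # band scene peaks at the equator
  scb <- scene_spec(seed = 6, n_frames = 2,
                    structures = list(structure_spec("band", speed_nm_s = 40)))
  mb <- render_equirect(scb, 1, n_theta = 90, n_phi = 180)
  prof <- latitude_intensity_profile(mb)
  expect_equal(prof$theta[which.max(prof$intensity)], pi / 2, tolerance = 0.08)
  # bitwise determinism with noise on
  m1 <- render_equirect(scb, 2, n_theta = 45, n_phi = 90)
  m2 <- render_equirect(scb, 2, n_theta = 45, n_phi = 90)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("stack and map renderers agree on the same scene", {
  sc <- scene_spec(seed = 4, n_frames = 1, noise = noiseless, structures = list(
    structure_spec("vortex", theta0 = pi / 3, speed_nm_s = 45)))
  stk <- render_stack(sc, 1, voxel_um = 0.6, shell_profile = "gaussian")
  mp <- project_equirectangular(stk, sc$geometry, n_theta = 60, n_phi = 120)
  me <- render_equirect(sc, 1, n_theta = 60, n_phi = 120)
  expect_gt(stats::cor(as.numeric(unclass(mp)), as.numeric(unclass(me))), 0.9)
  # a bare shell stack supports radius recovery
  sc0 <- scene_spec(seed = 7, structures = list(), noise = noiseless)
  g <- fit_sphere(render_stack(sc0, voxel_um = 0.5))
  expect_lt(abs(g$radius - 18), 0.5)
  expect_error(render_stack(sc0, extent_um = 10), "stack bounds")
})

test_that("the fixture suite carries all five kinds with coherent ground truth", {
  fx <- fixture_suite(seed = 11, n_frames = 3)
  expect_setequal(names(fx), c("stream", "vortex", "double_vortex", "band", "jammed"))
  expect_setequal(unique(sapply(fx, `[[`, "label")),
                  c("stream", "vortex", "band", "globally_jammed"))
  expect_true(validate_poincare_hopf(fx$band$defects)$pass)
  expect_true(validate_poincare_hopf(fx$jammed$defects)$pass)
  # generators are pure functions of (spec, seed)
  fx2 <- fixture_suite(seed = 11, n_frames = 3)
  expect_identical(unclass(fx$vortex$maps$maps[[2]]), unclass(fx2$vortex$maps$maps[[2]]))
  expect_identical(fx$jammed$defect_tracks[[1]]$xyz, fx2$jammed$defect_tracks[[1]]$xyz)
  # jammed pair-angle series stays stable over 30 minutes
  sc <- scene_spec(dt_s = 60, n_frames = 30, seed = 11, noise = noiseless)
  jam <- make_jammed_scene(sc)
  expect_lt(attr(jam$series, "sd_deg"), 2)
})
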