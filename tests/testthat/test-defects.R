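test_that("pair angles match axis cases and the tetrahedral reference", {
  g <- sphere_geometry(18)
  anti <- defect_configuration(c("+1", "+1"), g, theta = c(0, pi), phi = c(0, 0))
  expect_equal(pair_angles(anti), 180, tolerance = 1e-9)
  orth <- defect_configuration(c("+1/2", "+1/2"), g, theta = c(pi / 2, pi / 2),
                               phi = c(0, pi / 2), covers_full_surface = FALSE)
  expect_equal(pair_angles(orth), 90, tolerance = 1e-9)
  tet <- reference_configuration("tetrahedral", g)
  expect_equal(pair_angles(tet), rep(acos(-1 / 3) * 180 / pi, 6), tolerance = 1e-9)
  single <- defect_configuration("+1/2", g, theta = 1, phi = 1,
                                 covers_full_surface = FALSE)
  expect_error(pair_angles(single), "two defects")
})

test_that("mean pair angle agrees with a brute-force oracle on random configs", {
  g <- sphere_geometry(18)
  set.seed(13)
  for (i in 1:20) {
    u <- runif_sphere(4)
    cfg <- defect_configuration(rep("+1/2", 4), g, xyz = 18 * u)
    expect_equal(mean_pair_angle(cfg), mean(oracle_pair_angles_deg(18 * u)),
                 tolerance = 1e-9)
  }
})

test_that("reference configurations hit the printed tetrahedral/planar values", {
  expect_equal(round(mean_pair_angle(reference_configuration("tetrahedral")), 1), 109.5)
  expect_equal(mean_pair_angle(reference_configuration("planar")), 120, tolerance = 1e-9)
})

test_that("total charge is exact half-integer arithmetic", {
  g <- sphere_geometry(18)
  four_half <- reference_configuration("tetrahedral", g)
  expect_identical(total_charge(four_half), 2)
  two_one <- defect_configuration(c("+1", "+1"), g, theta = c(0, pi), phi = c(0, 0))
  expect_identical(total_charge(two_one), 2)
  one_half <- defect_configuration("+1/2", g, theta = 1, phi = 0,
                                   covers_full_surface = FALSE)
  expect_identical(total_charge(one_half), 0.5)
  mix <- defect_configuration(c("+1", "-1/2", "+1/2", "-1"), g,
                              theta = c(0.3, 1, 2, 2.8), phi = c(0, 1, 2, 3),
                              covers_full_surface = FALSE)
  expect_identical(total_charge(mix), 0)
  expect_error(defect_configuration("+3/2", g, theta = 1, phi = 0), "charge")
})

test_that("Poincare-Hopf validation binds only full-coverage configurations", {
  g <- sphere_geometry(18)
  expect_true(validate_poincare_hopf(reference_configuration("tetrahedral", g))$pass)
  band <- defect_configuration(c("+1", "+1"), g, theta = c(0, pi), phi = c(0, 0),
                               covers_full_surface = TRUE)
  expect_true(validate_poincare_hopf(band)$pass)
  short <- defect_configuration(c("+1/2", "+1/2"), g, theta = c(1, 2), phi = c(0, 1),
                                covers_full_surface = TRUE)
  expect_false(validate_poincare_hopf(short)$pass)
  # a defect-free or partial pattern is unconstrained
  partial <- defect_configuration("+1/2", g, theta = 1, phi = 0,
                                  covers_full_surface = FALSE)
  expect_true(validate_poincare_hopf(partial)$pass)
})

test_that("configuration classification separates tetrahedral, planar, intermediate", {
  expect_equal(classify_configuration(109.5, tol = 2), "tetrahedral")
  expect_equal(classify_configuration(120.0, tol = 2), "planar")
  expect_equal(classify_configuration(114.7, tol = 2), "intermediate")
  expect_error(classify_configuration(110, tol = 6), "disjoint")
  expect_error(classify_configuration(110, tol = 0), "disjoint")
})

test_that("mean pair angle is invariant under rotation and all relabelings", {
  g <- sphere_geometry(18)
  set.seed(17)
  u <- 18 * runif_sphere(4)
  m0 <- mean_pair_angle(defect_configuration(rep("+1/2", 4), g, xyz = u))
  rot <- rotation_matrix(stats::rnorm(3), 2.2)
  mR <- mean_pair_angle(defect_configuration(rep("+1/2", 4), g, xyz = rotate_points(u, rot)))
  expect_equal(mR, m0, tolerance = 1e-9)
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  expect_equal(nrow(perms), 24)
  for (i in seq_len(nrow(perms))) {
    mp <- mean_pair_angle(defect_configuration(rep("+1/2", 4), g,
                                               xyz = u[perms[i, ], ]))
    expect_equal(mp, m0, tolerance = 1e-12)
  }
})

test_that("uniformly random four-point configurations average 90-degree pair angles", {
  # under uniformity each pair angle has mean 90 degrees; sanity oracle for
  # both the sampler and the angle code
  set.seed(29)
  n <- 4000
  g <- sphere_geometry(1)
  means <- replicate(n %/% 100, {
    u <- runif_sphere(400)
    mean(sapply(seq_len(100), function(k)
      mean_pair_angle(defect_configuration(rep("+1/2", 4), g,
                                           xyz = u[(4 * k - 3):(4 * k), ]))))
  })
  expect_equal(mean(means), 90, tolerance = 0.012)  # +-1 degree
})

test_that("pair-angle series track configuration changes over time", {
  g <- sphere_geometry(18)
  t <- (0:9) * 60
  tet <- reference_configuration("tetrahedral", g)
  static_tracks <- lapply(1:4, function(d)
    trajectory(t, matrix(rep(tet$xyz[d, ], 10), 10, byrow = TRUE), g))
  s <- configuration_series(static_tracks)
  expect_equal(s$mean_angle_deg, rep(mean_pair_angle(tet), 10), tolerance = 1e-9)
  expect_equal(attr(s, "sd_deg"), 0, tolerance = 1e-12)
  # constructed oscillation between tetrahedral and planar arrangements
  beta_t <- acos(1 / sqrt(3))
  betas <- beta_t + (pi / 2 - beta_t) * (1 - cos(2 * pi * (0:9) / 10)) / 2
  osc_pos <- lapply(betas, function(b) {
    u <- rbind(c(sin(b), 0, cos(b)), c(-sin(b), 0, cos(b)),
               c(0, sin(b), -cos(b)), c(0, -sin(b), -cos(b)))
    18 * u
  })
  osc_tracks <- lapply(1:4, function(d)
    trajectory(t, do.call(rbind, lapply(osc_pos, function(p) p[d, ])), g))
  so <- configuration_series(osc_tracks)
  expect_equal(min(so$mean_angle_deg), 109.47, tolerance = 0.01)
  expect_equal(max(so$mean_angle_deg), 120, tolerance = 0.01)
  # mismatched time bases are rejected
  bad <- static_tracks
  bad[[4]] <- trajectory(t + 1, matrix(rep(tet$xyz[4, ], 10), 10, byrow = TRUE), g)
  expect_error(configuration_series(bad), "time bases")
})
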