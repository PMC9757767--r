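test_that("axial von Mises sampler covers uniform, concentrated and generic kappa", {
  expect_error(sample_orientations(10, -1), class = "parameter_error")
  expect_error(sample_orientations(0, 1), class = "parameter_error")

  # kappa = 0: uniform on (-90, 90]; window of +-20 deg holds ~41/180
  a <- sample_orientations(1e5, 0, seed = 1)
  expect_true(all(a > -90 & a <= 90))
  expect_lt(abs(mean(orientation_distance(a, 33) <= 20) - 41 / 180), 0.01)

  # degenerate limit: huge kappa collapses onto the mean angle
  b <- sample_orientations(1000, 1e4, mean_angle = -40, seed = 2)
  expect_true(all(orientation_distance(b, -40) <= 1))

  # kappa = 2: mean axial resultant matches the closed-form Bessel ratio
  # I1(k)/I0(k) (independent oracle for the doubled-angle von Mises law)
  th <- sample_orientations(2e5, 2, mean_angle = 10, seed = 3) * pi / 180
  rbar <- Mod(mean(exp(2i * th)))
  expect_equal(rbar, besselI(2, 1) / besselI(2, 0), tolerance = 0.01)
})

test_that("fiber-field renderer honours holes, emptiness and determinism", {
  expect_error(fiber_field_params(hole_fraction = 1), class = "parameter_error")
  expect_error(fiber_field_params(fiber_intensity = 10, background_level = 50),
               class = "parameter_error")
  expect_error(render_fiber_fov(fiber_field_params(), shape = c(32L, 32L)),
               class = "parameter_error")

  # holes cover half the area with zero background: flaggable by QC
  p <- fiber_field_params(hole_fraction = 0.5, background_level = 0, seed = 4)
  r <- render_fiber_fov(p, shape = c(128L, 128L))
  expect_gte(background_fraction(max_project(r$stack), 100), 0.4)
  expect_gte(mean(r$hole_mask), 0.5)

  # no fibers: pure background + diffuse lawn, no structure
  p0 <- fiber_field_params(fiber_count = 0, seed = 5)
  r0 <- render_fiber_fov(p0, shape = c(64L, 64L))
  expect_length(r0$angles, 0L)
  expect_true(all(r0$clean == r0$clean[1, 1]))

  # bit-for-bit reproducibility from identical params + seed
  a <- render_fiber_fov(fiber_field_params(seed = 6), shape = c(64L, 64L))
  b <- render_fiber_fov(fiber_field_params(seed = 6), shape = c(64L, 64L))
  expect_identical(a$stack, b$stack)
})

test_that("strongly anisotropic fields reproduce the planted mean angle", {
  modes <- sapply(1:5, function(s) {
    p <- fiber_field_params(kappa = 1e4, mean_angle = 30, seed = s,
                            fiber_count = 150)
    score_fov(max_project(render_fiber_fov(p, shape = c(128L, 128L))$stack))$mode_angle
  })
  expect_true(all(orientation_distance(modes, 30) <= 2))
})

test_that("expected alignment fraction is non-decreasing in kappa", {
  kappas <- c(0, 0.5, 1, 2, 4, 10)
  means <- sapply(kappas, function(k) {
    mean(sapply(1:20, function(s) {
      p <- fiber_field_params(kappa = k, mean_angle = 15, seed = 1000 + s,
                              fiber_count = 100)
      score_fov(max_project(render_fiber_fov(p, shape = c(96L, 96L),
                                             n_slices = 3L)$stack))$fraction_within_20
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("nuclei renderer places blobs with recorded truth centers", {
  # blank channel at count 0
  r0 <- render_nuclei_fov(0, seed = 1, shape = c(64L, 64L))
  expect_equal(nrow(r0$centers), 0L)
  expect_lt(max(max_project(r0$stack)), 150)   # background + noise only

  r <- render_nuclei_fov(10, radius_px = 8, seed = 2, shape = c(128L, 128L))
  expect_equal(nrow(r$centers), 10L)
  # all pairwise separations respect the non-overlap attempt
  d <- as.matrix(dist(r$centers))
  expect_gte(min(d[upper.tri(d)]), 2.2 * 8)

  # impossible packing reports a placement error
  expect_error(render_nuclei_fov(400, radius_px = 8, seed = 3,
                                 shape = c(64L, 64L)),
               class = "placement_error")
})

test_that("simulated screens have consistent manifests, truth and determinism", {
  eff <- data.frame(compound = "CPD-01", concentration = 1, kappa_mult = 0.1)
  cfg <- sim_screen_config(n_compounds = 4, concentrations = c(1, 10),
                           effects = eff, replicates = 3, n_negative = 2,
                           n_positive = 1, shape = c(64L, 64L),
                           nuclei_baseline = 8, nuclei_radius = 4,
                           master_seed = 9L)
  sim <- simulate_screen(cfg)
  n_wells <- 4 * 2 + 2 + 1
  expect_equal(nrow(sim$manifest), n_wells * 4 * 3)
  expect_equal(nrow(sim$truth), nrow(sim$manifest))
  # planted effect lands on the right condition only
  pl <- sim$truth$compound == "CPD-01" & sim$truth$concentration == 1
  expect_true(all(sim$truth$kappa_mult[pl] == 0.1))
  expect_true(all(sim$truth$kappa_mult[!pl & sim$truth$role == "test"] == 1))
  # negative controls share the high-kappa baseline; positive control reduced
  expect_true(all(sim$truth$kappa[sim$truth$role == "negative-control"] ==
                    cfg$kappa_baseline))
  expect_true(all(sim$truth$kappa[sim$truth$role == "positive-control"] ==
                    cfg$kappa_baseline * cfg$positive_kappa_mult))

  # same master seed: identical truth and identical pixels
  sim2 <- simulate_screen(cfg)
  expect_identical(sim$truth, sim2$truth)
  st1 <- simulate_fov(sim$truth[17, ], shape = cfg$shape, n_slices = 3L)
  st2 <- simulate_fov(sim2$truth[17, ], shape = cfg$shape, n_slices = 3L)
  expect_identical(st1$matrix_stack, st2$matrix_stack)
  expect_identical(st1$nuclei_stack, st2$nuclei_stack)

  # unknown compound in the effect table is a config error
  bad <- data.frame(compound = "NOPE", concentration = 1, kappa_mult = 0.5)
  expect_error(sim_screen_config(n_compounds = 2, effects = bad),
               class = "config_error")
})
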