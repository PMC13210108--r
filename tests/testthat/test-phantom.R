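test_that("static phantom is identical across phases and deterministic", {
  spec <- test_phantom_spec()
  ph <- generate_phantom(spec)
  expect_length(ph$masks, 5)
  for (p in 2:5) expect_identical(ph$masks[[p]], ph$masks[[1]])

  ph2 <- generate_phantom(spec)
  expect_identical(ph$masks, ph2$masks)

  noisy <- generate_phantom(test_phantom_spec(boundary_noise_sd = 0.2))
  noisy2 <- generate_phantom(test_phantom_spec(boundary_noise_sd = 0.2))
  expect_identical(noisy$masks, noisy2$masks)
  expect_false(identical(noisy$masks[[1]], ph$masks[[1]]))
})

test_that("phantom generation leaves the session RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_phantom(test_phantom_spec(boundary_noise_sd = 0.1)))
  expect_identical(.Random.seed, before)
})

test_that("pulsating phantom volume range matches the closed-form sphere range", {
  spec <- phantom_spec(sac_radius = 3, sac_center = c(0, 0, 4),
                       parent_radius = 1.2, voxel_spacing = 0.25,
                       n_phases = 20, global_pulsation_fraction = 0.02,
                       seed = 1)
  ph <- generate_phantom(spec)
  vols <- vapply(seq_len(20), function(p) mask_volume(phantom_phase(ph, p)), 0)
  measured_range <- max(vols) - min(vols)
  analytic_range <- 4 / 3 * pi * ((3 * 1.02)^3 - (3 * 0.98)^3)
  # voxel-count volumes carry aliasing error of the order of one voxel layer
  # fraction; 10% of the excursion is ample at 0.25 mm spacing
  expect_lt(abs(measured_range - analytic_range) / analytic_range, 0.10)
  expect_equal(ph$truth$sphere_volume_t[6], 4 / 3 * pi * (3 * 1.02)^3,
               tolerance = 1e-12)
})

test_that("focal patch area matches the analytic spherical cap", {
  theta0 <- 0.9
  analytic <- 2 * pi * 9 * (1 - cos(theta0))
  spec <- test_phantom_spec(focal_patch = list(center_direction = c(0, 0, 1),
                                               angular_radius = theta0,
                                               extra_amplitude = 0.5))
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$patch_area, analytic, tolerance = 1e-12)

  # mesh-measured area of the same cap on an analytic sphere
  mesh <- sphere_field_mesh(radius = 3, spacing = 0.12)
  ang <- acos(pmin(1, pmax(-1, mesh$vertices[, 3] /
                             sqrt(rowSums(mesh$vertices^2)))))
  measured <- sum(vertex_areas(mesh)[ang < theta0])
  expect_lt(abs(measured - analytic) / analytic, 0.05)
})

test_that("generated signals carry their ground truth", {
  const <- generate_signal(signal_spec(baseline_level = 7, n_phases = 20))
  expect_true(all(as.numeric(const) == 7))

  pure <- generate_signal(signal_spec(baseline_level = 5, harmonic_amplitude = 2,
                                      n_phases = 20))
  expect_equal(max(pure) - min(pure), 4, tolerance = 1e-12)
  fit <- fit_first_harmonic(pure)
  expect_equal(fit$pulsation_amplitude, 2, tolerance = 1e-9)
  expect_equal(fit$mean_level, 5, tolerance = 1e-9)

  s1 <- generate_signal(signal_spec(noise_sd = 1, seed = 5))
  s2 <- generate_signal(signal_spec(noise_sd = 1, seed = 5))
  expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("noisy harmonic amplitude is recovered on average", {
  amps <- vapply(1:500, function(s) {
    x <- generate_signal(signal_spec(harmonic_amplitude = 2, noise_sd = 0.3,
                                     n_phases = 20, seed = s))
    fit_first_harmonic(x)$pulsation_amplitude
  }, 0)
  expect_lt(abs(mean(amps) - 2) / 2, 0.05)
})

test_that("repeatability pairs have the variance-addition spread", {
  p0 <- generate_repeatability_pairs(10, 50, 0, seed = 1)
  expect_true(all(p0[, 1] == p0[, 2]))

  p1 <- generate_repeatability_pairs(10000, 50, 1, seed = 2)
  expect_lt(abs(sd(p1[, 2] - p1[, 1]) - sqrt(2)) / sqrt(2), 0.03)

  expect_identical(generate_repeatability_pairs(5, 1, 1, seed = 3),
                   generate_repeatability_pairs(5, 1, 1, seed = 3))
})
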