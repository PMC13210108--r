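test_that("size-change criterion reproduces the bundled cohort outcomes", {
  cohort <- classify_cohort_size_change(example_cohort())
  expect_equal(sum(cohort$changed), 6)
  expect_equal(sum(cohort$direction == "enlarged"), 5)
  expect_equal(sum(cohort$direction == "reduced"), 1)

  a1 <- assess_size_change(list(mean = 65.05, sd = 2.41),
                           list(mean = 81.59, sd = 1.40))
  expect_true(a1$changed)
  expect_equal(a1$direction, "enlarged")
  expect_equal(a1$threshold, 2 * sqrt(2.41^2 + 1.40^2), tolerance = 1e-12)

  a8 <- assess_size_change(list(mean = 31.08, sd = 0.59),
                           list(mean = 31.01, sd = 1.27))
  expect_false(a8$changed)
  expect_equal(a8$direction, "none")

  same <- phase_series(rep(5, 20))
  v <- assess_size_change(same, same)
  expect_false(v$changed)
  expect_equal(v$delta, 0)

  expect_error(assess_size_change(phase_series(1:20, "V_sac"),
                                  phase_series(1:20, "S_sac")),
               "different parameters")
})

test_that("robust noise sigma follows the MAD-of-differences formula", {
  expect_equal(estimate_noise_sigma(phase_series(rep(3, 20))), 0)

  alternating <- phase_series(rep(c(0, 1), length.out = 21))
  expect_equal(estimate_noise_sigma(alternating), 1 / (0.6745 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(estimate_noise_sigma(alternating, divisor = "half"),
               1 / (0.6745 * 2), tolerance = 1e-12)

  expect_error(estimate_noise_sigma(phase_series(c(1, 2, 3, 4))), "at least 5")

  # calibration: median estimate within 10% of the true noise SD
  sig <- vapply(1:10000, function(s) {
    set.seed(s)
    estimate_noise_sigma(phase_series(rnorm(20, 0, 2)))
  }, 0)
  expect_lt(abs(median(sig) - 2) / 2, 0.10)
})

test_that("GVP detection applies the noise threshold and the volume floor", {
  t_idx <- 0:19
  big <- phase_series(100 + 5 * sin(2 * pi * t_idx / 20) +
                        0.01 * sin(6 * pi * t_idx / 20 + 1))
  r <- detect_gvp(big)
  expect_true(r$present)
  expect_equal(r$amplitude, max(big) - min(big), tolerance = 1e-12)

  expect_false(detect_gvp(phase_series(rep(50, 20)))$present)

  small <- phase_series(100 + 1.25 * sin(2 * pi * t_idx / 20) +
                          0.001 * sin(6 * pi * t_idx / 20 + 1))
  rs <- detect_gvp(small)
  expect_false(rs$present)                          # fails the 3 mm^3 floor
  expect_gt(rs$amplitude / 2, 3 * rs$sigma_noise)   # despite passing 3 sigma
  expect_true(detect_gvp(small, volume_floor = 0.1)$present)
})

test_that("signal qualification reports range, noise and SNR", {
  q0 <- qualify_signal(phase_series(rep(2, 20)))
  expect_equal(q0$delta_x, 0)
  expect_false(q0$qualified)

  # varying signal whose inter-phase differences are MAD-zero: the noise
  # estimate vanishes and the SNR is reported as the +Inf sentinel
  step <- phase_series(c(rep(0, 10), rep(1, 10)))
  qs <- qualify_signal(step)
  expect_identical(qs$sd_noise, 0)
  expect_true(is.infinite(qs$snr))
  expect_true(qs$qualified)

  # a noiseless sinusoid still qualifies (large finite SNR: the
  # difference-based noise floor sees the harmonic slope, not zero)
  pure <- generate_signal(signal_spec(harmonic_amplitude = 2, n_phases = 20))
  qp <- qualify_signal(pure)
  expect_gt(qp$snr, 3)
  expect_true(qp$qualified)

  # SNR is monotone in amplitude at fixed noise and seed
  snr_at <- function(a) {
    s <- generate_signal(signal_spec(harmonic_amplitude = a, noise_sd = 1,
                                     n_phases = 20, seed = 9))
    qualify_signal(s)$snr
  }
  snrs <- vapply(c(0.5, 1, 2, 4), snr_at, 0)
  expect_true(all(diff(snrs) > 0))
})

test_that("first-harmonic decomposition is exact, orthogonal and conservative", {
  t_idx <- 0:19
  exact <- phase_series(5 + 2 * sin(2 * pi * t_idx / 20))
  fit <- fit_first_harmonic(exact)
  expect_equal(fit$mean_level, 5, tolerance = 1e-10)
  expect_equal(fit$pulsation_amplitude, 2, tolerance = 1e-10)
  expect_true(all(abs(fit$residuals) < 1e-10))

  second <- phase_series(sin(4 * pi * t_idx / 20))
  expect_lt(fit_first_harmonic(second)$pulsation_amplitude, 1e-10)

  noisy <- generate_signal(signal_spec(harmonic_amplitude = 2, noise_sd = 0.5,
                                       trend_slope = 0.05, seed = 4))
  f2 <- fit_first_harmonic(noisy)
  expect_equal(f2$fitted + f2$residuals, as.numeric(noisy), tolerance = 1e-12)

  # residual SD recovers the injected noise level on average
  res_sd <- vapply(1:1000, function(s) {
    x <- generate_signal(signal_spec(harmonic_amplitude = 2, noise_sd = 0.5,
                                     n_phases = 20, seed = s))
    sd(fit_first_harmonic(x)$residuals)
  }, 0)
  expect_lt(abs(mean(res_sd) - 0.5) / 0.5, 0.10)
})

test_that("measured pulsation amplitude is monotone in the injected amplitude", {
  amps <- vapply(c(0.5, 1, 2, 4), function(a) {
    x <- generate_signal(signal_spec(harmonic_amplitude = a, noise_sd = 0.5,
                                     n_phases = 20, seed = 21))
    fit_first_harmonic(x)$pulsation_amplitude
  }, 0)
  expect_true(all(diff(amps) > 0))
})

test_that("Bland-Altman MDC follows 1.96 SD of the differences", {
  ident <- cbind(1:10, 1:10)
  m <- compute_mdc(ident)
  expect_equal(m$bias, 0)
  expect_equal(m$mdc, 0)

  offset <- cbind(1:10, 1:10 + 1)
  mo <- compute_mdc(offset)
  expect_equal(mo$bias, 1)
  expect_equal(mo$mdc, 0)

  set.seed(2)
  pairs <- cbind(rnorm(10000), rnorm(10000))  # D ~ N(0, sqrt(2))
  mn <- compute_mdc(pairs)
  expect_lt(abs(mn$mdc - 1.96 * sqrt(2)) / (1.96 * sqrt(2)), 0.03)
  expect_equal(mn$loa_high - mn$loa_low, 2 * mn$mdc, tolerance = 1e-12)

  expect_error(compute_mdc(matrix(1, 1, 2)), "at least 2")
})

test_that("deformability is gated by the larger of MDC and noise floor", {
  series <- generate_signal(signal_spec(harmonic_amplitude = 2, noise_sd = 0.05,
                                        seed = 3))
  decomp <- fit_first_harmonic(series)
  qual <- qualify_signal(series)
  expect_true(qual$qualified)

  low <- classify_deformability(decomp, qual, mdc = 10, noise_floor = 0)
  expect_identical(low$status, "not_deformable")
  expect_false(low$deformability_present)

  hi <- classify_deformability(decomp, qual, mdc = 1e-6, noise_floor = 1e-6)
  expect_identical(hi$status, "deformable")

  unq <- qualify_signal(phase_series(rep(1, 20)))
  ne <- classify_deformability(decomp, unq, mdc = 0.1)
  expect_identical(ne$status, "not_evaluable")
  expect_true(is.na(ne$deformability_present))
})

test_that("non-periodic component three times the floor is declared deformable", {
  floor_mdc <- 0.2
  # square-wave component away from the fundamental: orthogonal to the
  # first-harmonic fit, so it survives into the residuals
  square <- 0.6 * sign(sin(6 * pi * (0:19) / 20 + 0.5))
  hits <- vapply(1:500, function(s) {
    x <- generate_signal(signal_spec(baseline_level = 50, harmonic_amplitude = 1,
                                     noise_sd = 0.1, n_phases = 20, seed = s))
    x <- phase_series(as.numeric(x) + square)
    d <- fit_first_harmonic(x)
    q <- qualify_signal(x)
    isTRUE(classify_deformability(d, q, mdc = floor_mdc)$deformability_present)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("SWP classification follows amplitude, area and fraction thresholds", {
  sphere <- uv_sphere_mesh(radius = 3, n_theta = 96, n_phi = 48)
  n <- nrow(sphere$vertices)
  area <- mesh_area(sphere)
  ang_to <- function(dir) {
    acos(pmin(1, pmax(-1, (sphere$vertices %*% dir) /
                        sqrt(rowSums(sphere$vertices^2)))))
  }

  zero <- detect_swp(synthetic_field(sphere, rep(0, n)), sac_area = area)
  expect_identical(zero$classification, "none")

  # one patch of ~10% of the surface at 0.5 mm
  th10 <- acos(1 - 0.2)    # cap fraction 10%
  amp <- ifelse(ang_to(c(0, 0, 1)) < th10, 0.5, 0)
  focal <- detect_swp(synthetic_field(sphere, amp), sac_area = area)
  expect_identical(focal$classification, "focal")
  expect_length(focal$regions, 1)
  expect_lt(abs(focal$pulsating_fraction - 0.10), 0.02)
  expect_gt(focal$regions[[1]]$peak_amplitude, 0.3)

  # two antipodal patches totalling ~25% -> heterogeneous
  th125 <- acos(1 - 0.25)
  amp2 <- ifelse(ang_to(c(0, 0, 1)) < th125 | ang_to(c(0, 0, -1)) < th125,
                 0.5, 0)
  het <- detect_swp(synthetic_field(sphere, amp2), sac_area = area)
  expect_identical(het$classification, "heterogeneous")
  expect_length(het$regions, 2)

  # sub-threshold amplitude never qualifies
  weak <- detect_swp(synthetic_field(sphere, rep(0.25, n)), sac_area = area)
  expect_identical(weak$classification, "none")

  # a qualifying patch below 5% of an (artificially large) sac area
  small <- detect_swp(synthetic_field(sphere, amp), sac_area = area * 3)
  expect_identical(small$classification, "none")
})

test_that("vertex areas sum to the mesh area", {
  m <- uv_sphere_mesh(radius = 2, n_theta = 32, n_phi = 16)
  expect_equal(sum(vertex_areas(m)), mesh_area(m), tolerance = 1e-9)
})
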