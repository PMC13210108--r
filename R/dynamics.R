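#' Phase-resolved geometric signal
#'
#' One geometric parameter of one examination sampled once per cardiac phase
#' (20 phases for a 5%-step R-R gating).
#'
#' @param values numeric vector, one value per phase (>= 4 finite values).
#' @param parameter_name label of the parameter (e.g. `"V_sac"`).
#' @return an object of class `phase_series`.
#' @export
phase_series <- function(values, parameter_name = "V_sac") {
  values <- as.numeric(values)
  if (length(values) < 4) stop("a phase series needs at least 4 phases")
  if (!all(is.finite(values))) stop("phase series contains non-finite values")
  structure(values, parameter = parameter_name, class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat("<phase_series> ", attr(x, "parameter"), ", ", length(x), " phases, ",
      "range [", signif(min(x), 5), ", ", signif(max(x), 5), "]\n", sep = "")
  invisible(x)
}

#' Longitudinal size-change classification
#'
#' A change in mean sac volume between baseline and follow-up is called
#' significant when it exceeds twice the combined phase-wise measurement
#' variability:
#' \deqn{|V_{mean,2} - V_{mean,1}| > 2 \sqrt{SD_1^2 + SD_2^2},}
#' with means and standard deviations (n-1 denominator) taken across the
#' cardiac phases of each examination.
#'
#' @param baseline,followup [phase_series()] of the same parameter, or
#'   summary lists `list(mean =, sd =)` when only mean +/- variability
#'   summaries are available.
#' @return an object of class `size_change_verdict`: `changed`, `direction`
#'   (`"enlarged"`, `"reduced"` or `"none"`), `delta`, `threshold`,
#'   `mean1`, `mean2`, `sd1`, `sd2`.
#' @export
assess_size_change <- function(baseline, followup) {
  summarise <- function(x) {
    if (inherits(x, "phase_series")) {
      list(mean = mean(x), sd = sd(x), parameter = attr(x, "parameter"))
    } else if (is.list(x) && all(c("mean", "sd") %in% names(x))) {
      list(mean = x$mean, sd = x$sd, parameter = x$parameter %||% NA_character_)
    } else stop("need a phase_series or a list(mean=, sd=)")
  }
  b <- summarise(baseline); f <- summarise(followup)
  if (!is.na(b$parameter) && !is.na(f$parameter) &&
      !identical(b$parameter, f$parameter)) {
    stop("baseline and follow-up series measure different parameters: ",
         b$parameter, " vs ", f$parameter)
  }
  delta <- f$mean - b$mean
  threshold <- 2 * sqrt(b$sd^2 + f$sd^2)
  changed <- abs(delta) > threshold
  structure(list(changed = changed,
                 direction = if (!changed) "none"
                             else if (delta > 0) "enlarged" else "reduced",
                 delta = delta, threshold = threshold,
                 mean1 = b$mean, mean2 = f$mean, sd1 = b$sd, sd2 = f$sd),
            class = "size_change_verdict")
}

#' @export
print.size_change_verdict <- function(x, ...) {
  cat("<size_change_verdict> ", if (x$changed) x$direction else "no change",
      " (delta ", signif(x$delta, 4), " vs threshold ",
      signif(x$threshold, 4), ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust noise SD from successive inter-phase differences
#'
#' First differences `d_i = V_{i+1} - V_i` are summarised by their median
#' absolute deviation (about the median); MAD/0.6745 is the
#' Gaussian-equivalent SD of the differences, and differencing independent
#' equal-variance noise doubles its variance, so the per-phase noise SD is by
#' default
#' \deqn{\sigma_{noise} = MAD(d) / (0.6745 \sqrt 2).}
#' The variant `divisor = "half"` applies a literal division by 2 instead of
#' by \eqn{\sqrt 2}.
#'
#' @param series a [phase_series()] with at least 5 phases.
#' @param divisor `"sqrt2"` (default) or `"half"`.
#' @return noise SD in the series' units.
#' @export
estimate_noise_sigma <- function(series, divisor = c("sqrt2", "half")) {
  divisor <- match.arg(divisor)
  if (length(series) < 5) stop("need at least 5 phases to estimate noise")
  d <- diff(as.numeric(series))
  m <- median(abs(d - median(d)))
  m / (0.6745 * if (divisor == "sqrt2") sqrt(2) else 2)
}

#' Global volumetric pulsation (GVP) detection
#'
#' The pulsation amplitude is measured on the raw phase-resolved sac volume
#' (no denoising is applied to the curve): the reported `amplitude` is the
#' peak-to-peak range `max(V) - min(V)`. Pulsation is present only if
#' * the peak-to-peak amplitude exceeds the resolution-limited minimum
#'   detectable volume change (3 mm^3 by default), and
#' * the oscillation amplitude exceeds `3 * sigma_noise`, the
#'   Gaussian-equivalent three-sigma criterion with the robust noise SD of
#'   [estimate_noise_sigma()].
#'
#' By default the three-sigma comparison uses the oscillation (half
#' peak-to-peak) amplitude, the amplitude convention under which a 3-sigma
#' gate actually gates: the raw range of 20 pure-noise phases already
#' averages 3.7 sigma, so comparing the full range against 3 sigma would
#' flag almost any noise-only series. `sigma_on = "peak_to_peak"` applies
#' the literal range instead.
#'
#' @param series a [phase_series()] of sac volume (mm^3).
#' @param volume_floor resolution floor in mm^3; set to 0 to disable.
#' @param sigma_factor multiple of the noise SD (3 = three-sigma rule).
#' @param divisor passed to [estimate_noise_sigma()].
#' @param sigma_on amplitude convention for the sigma criterion: `"half"`
#'   (oscillation amplitude, default) or `"peak_to_peak"`.
#' @return an object of class `gvp_result`: `present`, `amplitude`
#'   (peak-to-peak, mm^3), `sigma_noise`, `volume_floor`, `sigma_factor`,
#'   `sigma_on`.
#' @export
detect_gvp <- function(series, volume_floor = 3, sigma_factor = 3,
                       divisor = "sqrt2", sigma_on = c("half", "peak_to_peak")) {
  sigma_on <- match.arg(sigma_on)
  amplitude <- max(series) - min(series)
  sigma <- estimate_noise_sigma(series, divisor = divisor)
  amp_sigma <- if (sigma_on == "half") amplitude / 2 else amplitude
  present <- amp_sigma > sigma_factor * sigma && amplitude > volume_floor
  structure(list(present = present, amplitude = amplitude,
                 sigma_noise = sigma, volume_floor = volume_floor,
                 sigma_factor = sigma_factor, sigma_on = sigma_on),
            class = "gvp_result")
}

#' @export
print.gvp_result <- function(x, ...) {
  cat("<gvp_result> ", if (x$present) "present" else "absent",
      " (amplitude ", signif(x$amplitude, 4), " mm^3, 3*sigma ",
      signif(x$sigma_factor * x$sigma_noise, 4), ", floor ",
      x$volume_floor, " mm^3)\n", sep = "")
  invisible(x)
}

#' Dynamic signal qualification
#'
#' Screens a phase-resolved signal before dynamic interpretation: signal
#' range `dX = X_max - X_min`, robust noise SD, MAD of the signal, and
#' signal-to-noise ratio `SNR = dX / SD_noise`. A signal qualifies when
#' `SNR >= min_snr` and `dX > 0`; a noiseless varying signal has infinite
#' SNR and qualifies.
#'
#' @param series a [phase_series()].
#' @param min_snr minimum SNR (the screening threshold; 3 by default).
#' @param divisor passed to [estimate_noise_sigma()].
#' @return list with `delta_x`, `sd_noise`, `mad`, `snr`, `qualified`.
#' @export
qualify_signal <- function(series, min_snr = 3, divisor = "sqrt2") {
  delta_x <- max(series) - min(series)
  sd_noise <- estimate_noise_sigma(series, divisor = divisor)
  snr <- if (sd_noise == 0) {
    if (delta_x > 0) Inf else NA_real_
  } else delta_x / sd_noise
  list(delta_x = delta_x, sd_noise = sd_noise,
       mad = median(abs(series - median(series))),
       snr = snr,
       qualified = delta_x > 0 && (is.infinite(snr) || snr >= min_snr))
}

#' First-harmonic decomposition of a phase-resolved signal
#'
#' Least-squares fit of `X(t) = mu + a sin(2*pi*t/n) + b cos(2*pi*t/n)` over
#' the equally spaced cardiac phases `t = 0, ..., n-1`; with this spacing the
#' fit equals the first Fourier component, so a pure higher harmonic yields
#' zero amplitude. The pulsation amplitude is `sqrt(a^2 + b^2)`; residuals
#' are the measured signal minus the fit (fit + residuals reconstruct the
#' input exactly) and their MAD summarises the non-periodic variability.
#'
#' @param series a [phase_series()] (>= 4 phases).
#' @return an object of class `harmonic_decomposition`: `mean_level`,
#'   `pulsation_amplitude`, `harmonic_phase` (radians, such that the fit is
#'   `mu + A sin(2*pi*t/n + phase)`), `fitted`, `residuals`, `residual_mad`,
#'   plus the [qualify_signal()] fields `snr` and `qualified` filled by
#'   [run_examination()] workflows via [qualify_signal()].
#' @export
fit_first_harmonic <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  t_idx <- seq_len(n) - 1
  s <- sin(2 * pi * t_idx / n); co <- cos(2 * pi * t_idx / n)
  fit <- stats::lm.fit(cbind(mu = 1, s = s, co = co), x)
  coefs <- fit$coefficients
  amplitude <- sqrt(coefs[["s"]]^2 + coefs[["co"]]^2)
  fitted <- as.numeric(cbind(1, s, co) %*% coefs)
  residuals <- x - fitted
  structure(list(mean_level = coefs[["mu"]],
                 pulsation_amplitude = amplitude,
                 harmonic_phase = atan2(coefs[["co"]], coefs[["s"]]),
                 coefficients = coefs,
                 fitted = fitted, residuals = residuals,
                 residual_mad = median(abs(residuals - median(residuals)))),
            class = "harmonic_decomposition")
}

#' @export
print.harmonic_decomposition <- function(x, ...) {
  cat("<harmonic_decomposition> amplitude ", signif(x$pulsation_amplitude, 4),
      ", mean ", signif(x$mean_level, 5), ", residual MAD ",
      signif(x$residual_mad, 4), "\n", sep = "")
  invisible(x)
}

#' Bland-Altman repeatability and minimum detectable change
#'
#' From repeated measurement pairs: bias (mean difference), 95% limits of
#' agreement `bias +/- 1.96 SD(D)`, and the minimum detectable change
#' `MDC = 1.96 SD(D)` below which a measured change is indistinguishable
#' from measurement error.
#'
#' @param pairs numeric n x 2 matrix of paired measurements (n >= 2), e.g.
#'   from [generate_repeatability_pairs()].
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `mdc`.
#' @export
compute_mdc <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2 || ncol(pairs) != 2) {
    stop("need at least 2 measurement pairs (n x 2 matrix)")
  }
  d <- pairs[, 2] - pairs[, 1]
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, mdc = 1.96 * s)
}

#' Conservative deformability classification
#'
#' Residual (non-periodic) variability is interpreted as wall deformability
#' only when the residual MAD exceeds every measurement-uncertainty bound:
#' the Bland-Altman minimum detectable change and the noise floor, whichever
#' is larger. Signals that failed dynamic qualification are reported as
#' `"not_evaluable"` - an intentional exclusion by reliability criteria, not
#' a negative finding.
#'
#' @param decomposition a [fit_first_harmonic()] result.
#' @param qualification a [qualify_signal()] result for the same series.
#' @param mdc minimum detectable change (same units).
#' @param noise_floor additional noise floor (same units; 0 if none).
#' @return an object of class `deformability_verdict`: `status`
#'   (`"deformable"`, `"not_deformable"` or `"not_evaluable"`),
#'   `deformability_present` (logical, `NA` when not evaluable),
#'   `residual_mad`, `bound`.
#' @export
classify_deformability <- function(decomposition, qualification, mdc,
                                   noise_floor = 0) {
  stopifnot(inherits(decomposition, "harmonic_decomposition"))
  bound <- max(mdc, noise_floor)
  if (!isTRUE(qualification$qualified)) {
    return(structure(list(status = "not_evaluable",
                          deformability_present = NA,
                          residual_mad = decomposition$residual_mad,
                          bound = bound),
                     class = "deformability_verdict"))
  }
  present <- decomposition$residual_mad > bound
  structure(list(status = if (present) "deformable" else "not_deformable",
                 deformability_present = present,
                 residual_mad = decomposition$residual_mad, bound = bound),
            class = "deformability_verdict")
}

#' @export
print.deformability_verdict <- function(x, ...) {
  cat("<deformability_verdict> ", x$status, " (residual MAD ",
      signif(x$residual_mad, 4), " vs bound ", signif(x$bound, 4), ")\n",
      sep = "")
  invisible(x)
}
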