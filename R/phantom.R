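#' Specification of a pulsating sphere-on-vessel phantom
#'
#' Describes a saccular-aneurysm phantom for ECG-gated 4D acquisitions: a
#' spherical sac attached to a parent vessel built from cylindrical
#' half-lines meeting at the origin. Two opposite `branch_axes` give a
#' straight parent vessel (two branches at the neck); three axes give a
#' Y-junction (three branches), exercising the three-point neck-plane rule.
#'
#' The sac radius at phase `t` (0-based, `t = 0, ..., n_phases - 1`) is
#' `sac_radius * (1 + alpha * sin(2*pi*t/n_phases + offset))`. An optional
#' focal patch adds a radial offset `extra_amplitude * taper(theta) *
#' sin(2*pi*t/n_phases + offset)` inside the angular radius of the patch,
#' where `taper` is a raised cosine falling to zero at the patch rim; the
#' patch therefore pulsates with the cardiac cycle while the reference phase
#' (t = 0, the 0% R-R phase) is unperturbed when `offset = 0`. Boundary noise
#' jitters the implicit surface by a per-voxel, per-phase Gaussian offset.
#'
#' @param sac_radius sac radius in mm.
#' @param sac_center sac center (mm), relative to the vessel junction at the
#'   origin.
#' @param parent_radius parent vessel radius in mm (< `sac_radius`).
#' @param branch_axes list of direction vectors (half-lines from the origin).
#' @param voxel_spacing isotropic voxel spacing in mm.
#' @param n_phases number of cardiac phases (20 for a 5%-step R-R gating).
#' @param global_pulsation_fraction dimensionless radial amplitude `alpha`.
#' @param pulsation_phase_offset phase offset in radians.
#' @param focal_patch `NULL`, a single patch, or a list of patches. A patch
#'   is a list with `center_direction` (unit vector from the sac center),
#'   `angular_radius` (radians), `extra_amplitude` (mm) and optionally
#'   `phase_offset` (radians, default 0). Two patches driven in antiphase
#'   (`phase_offset = pi` on one of them) deform the wall at essentially
#'   constant sac volume - the shape-change-without-volume-change regime that
#'   dissociates spatial from global volumetric pulsation.
#' @param boundary_noise_sd boundary jitter SD in mm.
#' @param seed integer RNG seed; the generator is a pure function of the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(sac_radius = 3, sac_center = c(0, 0, 4),
                         parent_radius = 1.2,
                         branch_axes = list(c(1, 0, 0), c(-1, 0, 0)),
                         voxel_spacing = 0.25, n_phases = 20,
                         global_pulsation_fraction = 0,
                         pulsation_phase_offset = 0,
                         focal_patch = NULL, boundary_noise_sd = 0,
                         seed = 1L) {
  stopifnot(sac_radius > parent_radius, parent_radius > 0, n_phases >= 4,
            global_pulsation_fraction >= 0, voxel_spacing > 0,
            boundary_noise_sd >= 0, length(branch_axes) >= 1)
  if (!is.null(focal_patch)) {
    if (!is.null(focal_patch$center_direction)) focal_patch <- list(focal_patch)
    focal_patch <- lapply(focal_patch, function(p) {
      stopifnot(is.list(p),
                all(c("center_direction", "angular_radius", "extra_amplitude")
                    %in% names(p)),
                p$angular_radius > 0, p$extra_amplitude >= 0)
      p$center_direction <- normalize(p$center_direction)
      p$phase_offset <- p$phase_offset %||% 0
      p
    })
  }
  structure(list(sac_radius = sac_radius, sac_center = as.numeric(sac_center),
                 parent_radius = parent_radius,
                 branch_axes = lapply(branch_axes, normalize),
                 voxel_spacing = voxel_spacing, n_phases = as.integer(n_phases),
                 global_pulsation_fraction = global_pulsation_fraction,
                 pulsation_phase_offset = pulsation_phase_offset,
                 focal_patch = focal_patch,
                 boundary_noise_sd = boundary_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phase-resolved 4D phantom
#'
#' Voxelises the phantom of a [phantom_spec()] at each cardiac phase. The
#' result is deterministic for a fixed spec (the RNG state of the session is
#' left untouched).
#'
#' @param spec a [phantom_spec()].
#' @param margin_mm empty margin around the phantom, in mm.
#' @return an object of class `phase_volume_4d`: `masks` (list of logical 3D
#'   arrays), `spacing`, `origin`, `spec`, and `truth` (analytic per-phase sac
#'   radii and sphere volumes, and the analytic patch area when present).
#' @export
generate_phantom <- function(spec, margin_mm = 1.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_spacing
  amax <- spec$sac_radius * (1 + spec$global_pulsation_fraction) +
    (if (!is.null(spec$focal_patch))
       max(vapply(spec$focal_patch, `[[`, 0, "extra_amplitude")) else 0)
  ext <- amax + margin_mm
  lo <- pmin(spec$sac_center - ext, -spec$parent_radius - margin_mm)
  hi <- pmax(spec$sac_center + ext, spec$parent_radius + margin_mm)
  for (ax in spec$branch_axes) {  # tube runs to the grid border along its axis
    lo <- pmin(lo, ax * 4 * spec$sac_radius - spec$parent_radius - margin_mm)
    hi <- pmax(hi, ax * 4 * spec$sac_radius + spec$parent_radius + margin_mm)
  }
  dims <- pmax(ceiling((hi - lo) / h) + 1L, 8L)
  if (prod(dims) > 6e7) stop("phantom grid too large (", prod(dims),
                             " voxels); increase voxel_spacing")
  origin <- lo
  gx <- origin[1] + (seq_len(dims[1]) - 1) * h
  gy <- origin[2] + (seq_len(dims[2]) - 1) * h
  gz <- origin[3] + (seq_len(dims[3]) - 1) * h
  xs <- rep(gx, times = dims[2] * dims[3])
  ys <- rep(rep(gy, each = dims[1]), times = dims[3])
  zs <- rep(gz, each = dims[1] * dims[2])

  # static tube membership (union of capsule half-lines from the origin)
  tube <- rep(FALSE, length(xs))
  for (ax in spec$branch_axes) {
    tproj <- pmax(xs * ax[1] + ys * ax[2] + zs * ax[3], 0)
    d2 <- (xs - tproj * ax[1])^2 + (ys - tproj * ax[2])^2 + (zs - tproj * ax[3])^2
    tube <- tube | d2 <= spec$parent_radius^2
  }

  dxs <- xs - spec$sac_center[1]
  dys <- ys - spec$sac_center[2]
  dzs <- zs - spec$sac_center[3]
  rdist <- sqrt(dxs^2 + dys^2 + dzs^2)
  tapers <- lapply(spec$focal_patch, function(p) {
    cd <- p$center_direction
    costheta <- ifelse(rdist > 0, (dxs * cd[1] + dys * cd[2] + dzs * cd[3]) / rdist, 1)
    theta <- acos(pmin(pmax(costheta, -1), 1))
    taper <- rep(0, length(xs))
    inside <- theta < p$angular_radius
    taper[inside] <- 0.5 * (1 + cos(pi * theta[inside] / p$angular_radius))
    taper
  })

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_phases
  t_idx <- seq_len(n) - 1L
  s_t <- sin(2 * pi * t_idx / n + spec$pulsation_phase_offset)
  r_t <- spec$sac_radius * (1 + spec$global_pulsation_fraction * s_t)
  masks <- vector("list", n)
  for (p in seq_len(n)) {
    radius_dir <- r_t[p]
    for (k in seq_along(tapers)) {
      pk <- spec$focal_patch[[k]]
      radius_dir <- radius_dir + pk$extra_amplitude * tapers[[k]] *
        sin(2 * pi * t_idx[p] / n + spec$pulsation_phase_offset +
            pk$phase_offset)
    }
    thresholded <- rdist <= radius_dir
    if (spec$boundary_noise_sd > 0) {
      # jitter only a band around the surface (segmentation boundary noise,
      # not far-field speckle), then keep the largest connected component so
      # the emitted mask is a usable segmentation
      band <- which(abs(rdist - radius_dir) <= 3 * spec$boundary_noise_sd + h)
      thresholded[band] <- rdist[band] <= radius_dir[if (length(radius_dir) > 1)
                                                       band else 1] +
        rnorm(length(band), 0, spec$boundary_noise_sd)
    }
    m <- thresholded | tube
    dim(m) <- dims
    if (spec$boundary_noise_sd > 0) {
      comp <- .connected_components26(m)
      if (comp$n > 1) {
        biggest <- which.max(tabulate(comp$labels[comp$labels > 0], comp$n))
        m <- comp$labels == biggest
        dim(m) <- dims
      }
    }
    masks[[p]] <- m
  }

  truth <- list(sac_radius_t = r_t,
                sphere_volume_t = 4 / 3 * pi * r_t^3,
                patch_area = if (!is.null(spec$focal_patch))
                  vapply(spec$focal_patch, function(p) {
                    2 * pi * spec$sac_radius^2 * (1 - cos(p$angular_radius))
                  }, 0) else NA_real_)
  structure(list(masks = masks, spacing = rep(h, 3), origin = origin,
                 spec = spec, truth = truth),
            class = "phase_volume_4d")
}

#' @export
print.phase_volume_4d <- function(x, ...) {
  cat("<phase_volume_4d> ", length(x$masks), " phases, ",
      paste(dim(x$masks[[1]]), collapse = " x "), " voxels @ ",
      signif(x$spacing[1], 4), " mm\n", sep = "")
  invisible(x)
}

#' Extract one phase as a binary volume
#' @param phantom a [generate_phantom()] result.
#' @param phase 1-based phase index.
#' @return a [binary_volume()].
#' @export
phantom_phase <- function(phantom, phase) {
  stopifnot(inherits(phantom, "phase_volume_4d"),
            phase >= 1, phase <= length(phantom$masks))
  binary_volume(phantom$masks[[phase]], phantom$spacing, phantom$origin)
}

#' Export a 4D phantom as per-phase NRRD files plus a ground-truth sidecar
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @param encoding NRRD encoding, see [write_nrrd()].
#' @return character vector of file paths, invisibly.
#' @export
export_phantom_nrrd <- function(phantom, dir, encoding = "gzip") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in seq_along(phantom$masks)) {
    f <- file.path(dir, sprintf("phase_%02d.nrrd", p - 1))
    write_nrrd(phantom_phase(phantom, p), f, encoding = encoding)
    paths <- c(paths, f)
  }
  sidecar <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(spec = unclass(phantom$spec)[setdiff(names(phantom$spec), "focal_patch")],
         focal_patch = phantom$spec$focal_patch,
         truth = phantom$truth),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, sidecar))
}

#' Specification of a synthetic phase-resolved geometric signal
#'
#' @param baseline_level mean level (units of the measured parameter,
#'   e.g. mm^3 for a sac volume).
#' @param harmonic_amplitude amplitude of the first-harmonic component.
#' @param harmonic_phase phase of the harmonic, radians.
#' @param trend_slope linear drift per phase.
#' @param noise_sd Gaussian noise SD.
#' @param n_phases number of phases (>= 4).
#' @param seed RNG seed.
#' @return an object of class `signal_spec`.
#' @export
signal_spec <- function(baseline_level = 50, harmonic_amplitude = 0,
                        harmonic_phase = 0, trend_slope = 0, noise_sd = 0,
                        n_phases = 20, seed = 1L) {
  stopifnot(n_phases >= 4, noise_sd >= 0)
  structure(list(baseline_level = baseline_level,
                 harmonic_amplitude = harmonic_amplitude,
                 harmonic_phase = harmonic_phase, trend_slope = trend_slope,
                 noise_sd = noise_sd, n_phases = as.integer(n_phases),
                 seed = as.integer(seed)),
            class = "signal_spec")
}

#' Generate a phase-resolved signal with known ground truth
#'
#' `X(t) = baseline + A sin(2*pi*t/n + phi) + slope*t + e_t`, `t = 0, ...,
#' n-1`, `e_t ~ N(0, noise_sd^2)` seeded. The noiseless components are kept
#' in the `truth` attribute.
#'
#' @param spec a [signal_spec()].
#' @param parameter_name label of the measured parameter.
#' @return a [phase_series()] with a `truth` attribute.
#' @export
generate_signal <- function(spec, parameter_name = "V_sac") {
  stopifnot(inherits(spec, "signal_spec"))
  t_idx <- seq_len(spec$n_phases) - 1
  harmonic <- spec$harmonic_amplitude *
    sin(2 * pi * t_idx / spec$n_phases + spec$harmonic_phase)
  trend <- spec$trend_slope * t_idx
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  noise <- if (spec$noise_sd > 0) rnorm(spec$n_phases, 0, spec$noise_sd)
           else rep(0, spec$n_phases)
  out <- phase_series(spec$baseline_level + harmonic + trend + noise,
                      parameter_name)
  attr(out, "truth") <- list(harmonic = harmonic, trend = trend, noise = noise,
                             spec = spec)
  out
}

#' Seeded repeated-measurement pairs for repeatability analysis
#'
#' Each pair is the same true value observed twice with independent Gaussian
#' measurement error, as consumed by the Bland-Altman minimum-detectable-change
#' estimation.
#'
#' @param n_pairs number of pairs (>= 2).
#' @param true_value underlying value (e.g. mm^3).
#' @param measurement_sd per-measurement error SD.
#' @param seed RNG seed.
#' @return numeric `n_pairs` x 2 matrix with columns `m1`, `m2`.
#' @export
generate_repeatability_pairs <- function(n_pairs, true_value, measurement_sd,
                                         seed = 1L) {
  stopifnot(n_pairs >= 2, measurement_sd >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  m <- matrix(true_value + rnorm(2 * n_pairs, 0, measurement_sd), ncol = 2)
  colnames(m) <- c("m1", "m2")
  m
}

#' Write a phase series as CSV (`phase_index`, `value`)
#' @param series a [phase_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(series, path) {
  write.csv(data.frame(phase_index = seq_along(series) - 1,
                       value = as.numeric(series)),
            path, row.names = FALSE)
  invisible(path)
}
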