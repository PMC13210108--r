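#' Pipeline configuration
#'
#' All analysis thresholds in one place, with the conservative defaults of
#' the detection framework: 180 HU segmentation threshold, [3,3,3] box
#' smoothing with 5x linear refinement and a 0.5 isosurface, a 3 mm^3
#' resolution floor and 3-sigma noise rule for global volumetric pulsation,
#' 0.3 mm / 5 mm^2 / 5% / 20% spatial-pulsation thresholds, and a minimum
#' SNR of 3 for dynamic qualification. Every threshold that appears in a
#' report equals the configured value.
#'
#' @param hu_threshold segmentation threshold (HU).
#' @param resample_factor linear refinement factor per axis.
#' @param iso_level isosurface level on the smoothed occupancy volume.
#' @param gvp_volume_floor resolution floor for GVP (mm^3).
#' @param sigma_factor noise multiple for GVP.
#' @param sigma_divisor `"sqrt2"` or `"half"`, see [estimate_noise_sigma()].
#' @param swp_amp,swp_area,swp_fraction,swp_hetero SWP thresholds
#'   (mm, mm^2, fractions).
#' @param min_snr dynamic-qualification SNR threshold.
#' @param nsi_constant isoperimetric constant for the NSI.
#' @param displacement_on `"sac"` (default) or `"sacpar"`: mesh on which the
#'   displacement field is computed.
#' @param reference_phase 1-based reference phase (1 = 0% R-R).
#' @param mdc minimum detectable change for deformability gating (units of
#'   the analysed signal), or `NA` to skip the gate.
#' @param noise_floor additional deformability noise floor.
#' @return an object of class `run_config`.
#' @export
run_config <- function(hu_threshold = 180, resample_factor = 5,
                       iso_level = 0.5, gvp_volume_floor = 3,
                       sigma_factor = 3, sigma_divisor = "sqrt2",
                       swp_amp = 0.3, swp_area = 5, swp_fraction = 0.05,
                       swp_hetero = 0.20, min_snr = 3,
                       nsi_constant = (36 * pi)^(1 / 3),
                       displacement_on = c("sac", "sacpar"),
                       reference_phase = 1, mdc = NA_real_,
                       noise_floor = 0) {
  displacement_on <- match.arg(displacement_on)
  cfg <- list(hu_threshold = hu_threshold, resample_factor = resample_factor,
              iso_level = iso_level, gvp_volume_floor = gvp_volume_floor,
              sigma_factor = sigma_factor, sigma_divisor = sigma_divisor,
              swp_amp = swp_amp, swp_area = swp_area,
              swp_fraction = swp_fraction, swp_hetero = swp_hetero,
              min_snr = min_snr, nsi_constant = nsi_constant,
              displacement_on = displacement_on,
              reference_phase = as.integer(reference_phase),
              mdc = mdc, noise_floor = noise_floor)
  num <- unlist(cfg[c("hu_threshold", "resample_factor", "gvp_volume_floor",
                      "sigma_factor", "swp_amp", "swp_area", "swp_fraction",
                      "swp_hetero", "min_snr")])
  if (any(num <= 0)) stop("all thresholds must be > 0")
  structure(cfg, class = "run_config")
}

#' Read / write a configuration as JSON
#' @param path file path.
#' @return [run_config()] / `path` invisibly.
#' @export
read_config_json <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- vals[names(vals) %in% names(formals(run_config))]
  vals$mdc <- if (is.null(vals$mdc)) NA_real_ else as.numeric(vals$mdc)
  do.call(run_config, vals)
}

#' @rdname read_config_json
#' @param config a [run_config()].
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Analyse one phase-resolved examination
#'
#' Full single-examination pipeline on a 4D segmentation: per-phase surface
#' extraction (box smoothing, linear refinement, marching-tetrahedra
#' isosurface), centerline and neck-plane construction on the reference
#' phase, sac isolation at the neck plane (held fixed across phases),
#' phase-resolved sac volumes, global volumetric pulsation, per-vertex
#' displacement mapping with spatial-pulsation classification, morphology,
#' and first-harmonic decomposition with conservative deformability gating.
#'
#' @param phases a `phase_volume_4d` (from [generate_phantom()]), or a list
#'   of [binary_volume()]/[scalar_volume()] objects, one per phase
#'   (grey-valued volumes are thresholded at `config$hu_threshold`).
#' @param config a [run_config()].
#' @param examination_id identifier used in reports.
#' @return an object of class `examination_report`: `volume_series`
#'   ([phase_series()] of V_sac), `gvp` ([detect_gvp()]), `swp`
#'   ([detect_swp()]), `displacement` ([compute_displacement()]), `geometry`
#'   ([direct_parameters()]), `indices` ([ratio_indices()]),
#'   `qualification`, `decomposition`, `deformability`, `neck_plane`,
#'   `centerline`, `sac_mesh`, `config`.
#' @export
run_examination <- function(phases, config = run_config(),
                            examination_id = "exam") {
  stopifnot(inherits(config, "run_config"))
  if (inherits(phases, "phase_volume_4d")) {
    vols <- lapply(seq_along(phases$masks), function(p) phantom_phase(phases, p))
  } else {
    vols <- lapply(phases, function(v) {
      if (inherits(v, "scalar_volume")) threshold_segment(v, config$hu_threshold)
      else v
    })
  }
  n_phase <- length(vols)
  stopifnot(n_phase >= 4)
  ref <- config$reference_phase
  stopifnot(ref >= 1, ref <= n_phase)

  meshes <- lapply(vols, function(v) {
    extract_isosurface(smooth_and_resample(v, factor = config$resample_factor),
                       level = config$iso_level)
  })

  # centerlines come from the box-smoothed, re-binarised reference volume:
  # smoothing precedes key-point extraction in the processing chain, and
  # thinning a raw noisy mask yields spurious skeleton branches
  sm_ref <- smooth_and_resample(vols[[ref]], factor = 1)
  cmask <- binary_volume(sm_ref$data >= config$iso_level,
                         sm_ref$spacing, sm_ref$origin)
  centerline <- extract_centerline(cmask)
  plane <- identify_neck_plane(centerline, meshes[[ref]])
  pieces <- cut_sac(meshes[[ref]], plane)

  sac_meshes <- lapply(meshes, function(m) cut_sac(m, plane)$sac)
  v_sac <- vapply(sac_meshes, mesh_volume, 0)
  series <- phase_series(v_sac, "V_sac")

  gvp <- detect_gvp(series, volume_floor = config$gvp_volume_floor,
                    sigma_factor = config$sigma_factor,
                    divisor = config$sigma_divisor)

  disp_meshes <- if (config$displacement_on == "sac") sac_meshes else meshes
  disp_ref <- if (config$displacement_on == "sac") pieces$sac else meshes[[ref]]
  field <- compute_displacement(disp_ref, disp_meshes)
  swp <- detect_swp(field, sac_area = mesh_area(pieces$sac),
                    amp_threshold = config$swp_amp,
                    area_threshold = config$swp_area,
                    fraction_threshold = config$swp_fraction,
                    hetero_fraction = config$swp_hetero)

  geometry <- direct_parameters(pieces$sac, meshes[[ref]], plane)
  parent_d <- estimate_parent_diameter(centerline, geometry$N_max)
  indices <- ratio_indices(geometry, pieces$sac, parent_d,
                           nsi_constant = config$nsi_constant)

  qualification <- qualify_signal(series, min_snr = config$min_snr,
                                  divisor = config$sigma_divisor)
  decomposition <- fit_first_harmonic(series)
  deformability <- if (is.na(config$mdc)) NULL else
    classify_deformability(decomposition, qualification, config$mdc,
                           config$noise_floor)

  structure(list(examination_id = examination_id,
                 volume_series = series, gvp = gvp, swp = swp,
                 displacement = field, geometry = geometry, indices = indices,
                 qualification = qualification, decomposition = decomposition,
                 deformability = deformability,
                 neck_plane = plane, centerline = centerline,
                 sac_mesh = pieces$sac, parent_diameter = parent_d,
                 config = config),
            class = "examination_report")
}

#' @export
print.examination_report <- function(x, ...) {
  cat("<examination_report> ", x$examination_id, "\n  V_sac ",
      signif(mean(x$volume_series), 5), " mm^3 (range ",
      signif(max(x$volume_series) - min(x$volume_series), 4), "), GVP ",
      if (x$gvp$present) "present" else "absent", ", SWP ",
      x$swp$classification, "\n", sep = "")
  invisible(x)
}

#' Cohort-level association analysis
#'
#' Builds the pulsation-by-size-change 2x2 tables from per-examination
#' outcomes and runs the exploratory statistics battery on each.
#'
#' @param outcomes `data.frame` with logical columns `swp_present`,
#'   `gvp_present`, `size_changed` (one row per aneurysm).
#' @return an object of class `cohort_report`: `tables`
#'   ([contingency_2x2()] per exposure), `statistics`
#'   ([association_statistics()] per exposure), `outcomes`.
#' @export
run_cohort <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  tables <- cohort_association_tables(outcomes)
  structure(list(tables = tables,
                 statistics = lapply(tables, association_statistics),
                 outcomes = outcomes),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> ", nrow(x$outcomes), " aneurysms\n", sep = "")
  for (nm in names(x$statistics)) {
    s <- x$statistics[[nm]]
    cat("  ", nm, ": Fisher p = ", signif(s$fisher_p, 3), ", OR = ",
        signif(s$odds_ratio$point, 3), " (", signif(s$odds_ratio$ci_low, 3),
        ", ", signif(s$odds_ratio$ci_high, 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Recompute the bundled-cohort results
#'
#' Runs the complete desk-scale analysis on the bundled example cohort:
#' size-change classification of all eleven aneurysms, cohort descriptives,
#' exact association statistics for both pulsation tables, and the
#' standardised ELAPSS group difference.
#'
#' @return list with `cohort` (classified), `n_changed`, `n_enlarged`,
#'   `n_reduced`, `descriptives`, `tables`, `statistics`, `elapss_g`.
#' @export
reproduce_study_fixtures <- function() {
  cohort <- classify_cohort_size_change(example_cohort())
  tables <- example_pulsation_tables()
  gr <- example_elapss_groups()
  i1 <- which(gr$group == "size_change"); i2 <- which(gr$group == "stable")
  list(cohort = cohort,
       n_changed = sum(cohort$changed),
       n_enlarged = sum(cohort$direction == "enlarged"),
       n_reduced = sum(cohort$direction == "reduced"),
       descriptives = cohort_descriptives(cohort),
       tables = tables,
       statistics = lapply(tables, association_statistics),
       elapss_g = hedges_g(gr$mean[i1], gr$sd[i1], gr$n[i1],
                           gr$mean[i2], gr$sd[i2], gr$n[i2]))
}

#' Flat one-row summary of an examination report
#'
#' @param report an [run_examination()] result.
#' @return one-row `data.frame` suitable for CSV export.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "examination_report"))
  data.frame(examination_id = report$examination_id,
             v_sac_mean = mean(report$volume_series),
             v_sac_range = max(report$volume_series) - min(report$volume_series),
             gvp_present = report$gvp$present,
             gvp_amplitude = report$gvp$amplitude,
             gvp_sigma_noise = report$gvp$sigma_noise,
             swp_class = report$swp$classification,
             swp_fraction = report$swp$pulsating_fraction,
             pulsation_amplitude = report$decomposition$pulsation_amplitude,
             residual_mad = report$decomposition$residual_mad,
             snr = report$qualification$snr,
             qualified = report$qualification$qualified,
             UI = report$indices$UI, NSI = report$indices$NSI,
             AR = report$indices$AR, SR = report$indices$SR,
             BF = report$indices$BF, CP = report$indices$CP,
             V_sac = report$geometry$V_sac, S_sac = report$geometry$S_sac,
             N_max = report$geometry$N_max)
}

#' Write an examination report (JSON + flat CSV row + PLY amplitude map)
#'
#' @param report an [run_examination()] result.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_examination_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  row <- report_row(report)
  csv <- file.path(dir, paste0(report$examination_id, "_summary.csv"))
  write.csv(row, csv, row.names = FALSE)
  js <- file.path(dir, paste0(report$examination_id, "_report.json"))
  jsonlite::write_json(
    list(examination_id = report$examination_id,
         volume_series = as.numeric(report$volume_series),
         gvp = report$gvp[c("present", "amplitude", "sigma_noise",
                            "volume_floor")],
         swp = list(classification = report$swp$classification,
                    pulsating_area_total = report$swp$pulsating_area_total,
                    pulsating_fraction = report$swp$pulsating_fraction),
         decomposition = report$decomposition[c("mean_level",
                                                "pulsation_amplitude",
                                                "residual_mad")],
         qualification = report$qualification,
         thresholds = unclass(report$config)),
    js, auto_unbox = TRUE, digits = NA, null = "null")
  ply <- file.path(dir, paste0(report$examination_id, "_amplitude.ply"))
  write_ply(report$displacement$reference_mesh, ply,
            scalar = report$displacement$amplitude)
  invisible(c(csv, js, ply))
}
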