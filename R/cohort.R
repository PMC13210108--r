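#' Bundled example cohort
#'
#' Baseline and follow-up measurements of eleven unruptured saccular
#' intracranial aneurysms in ten patients followed over 2-6 years: maximal
#' size and sac volume as mean +/- phase-wise measurement variability across
#' the 20 cardiac phases of each ECG-gated examination, follow-up interval,
#' and the ELAPSS-predicted 3-year growth risk.
#'
#' @return a `data.frame`, one row per aneurysm.
#' @export
example_cohort <- function() {
  read.csv(system.file("extdata", "cohort_volumes.csv", package = "wallpulse"),
           stringsAsFactors = FALSE)
}

#' Bundled baseline-pulsation versus size-change tables
#'
#' The two 2x2 layouts relating baseline pulsation status (spatial wall
#' pulsation, global volumetric pulsation) to the longitudinal size-change
#' outcome in the example cohort.
#'
#' @return named list of [contingency_2x2()] objects
#'   (`swp_vs_size_change`, `gvp_vs_size_change`).
#' @export
example_pulsation_tables <- function() {
  df <- read.csv(system.file("extdata", "pulsation_tables.csv",
                             package = "wallpulse"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    contingency_2x2(df$a[i], df$b[i], df$c[i], df$d[i])
  })
  names(out) <- df$table
  out
}

#' Bundled ELAPSS summaries by size-change outcome
#'
#' @return `data.frame` with columns `group`, `mean`, `sd`, `n`.
#' @export
example_elapss_groups <- function() {
  read.csv(system.file("extdata", "elapss_groups.csv", package = "wallpulse"),
           stringsAsFactors = FALSE)
}

#' Size-change classification of a volume cohort
#'
#' Applies the longitudinal size-change criterion of [assess_size_change()]
#' to every aneurysm of a cohort table with columns `vol_bl_mm3`,
#' `vol_bl_sd`, `vol_fu_mm3`, `vol_fu_sd` (means and phase-wise SDs).
#'
#' @param cohort a `data.frame` like [example_cohort()].
#' @return the cohort with added columns `delta`, `threshold`, `changed`,
#'   `direction`.
#' @export
classify_cohort_size_change <- function(cohort) {
  stopifnot(all(c("vol_bl_mm3", "vol_bl_sd", "vol_fu_mm3", "vol_fu_sd")
                %in% names(cohort)))
  verdicts <- lapply(seq_len(nrow(cohort)), function(i) {
    assess_size_change(list(mean = cohort$vol_bl_mm3[i], sd = cohort$vol_bl_sd[i]),
                       list(mean = cohort$vol_fu_mm3[i], sd = cohort$vol_fu_sd[i]))
  })
  cohort$delta <- vapply(verdicts, `[[`, 0, "delta")
  cohort$threshold <- vapply(verdicts, `[[`, 0, "threshold")
  cohort$changed <- vapply(verdicts, `[[`, TRUE, "changed")
  cohort$direction <- vapply(verdicts, `[[`, "", "direction")
  cohort
}

#' Cohort descriptive statistics
#'
#' @param cohort a `data.frame` like [example_cohort()].
#' @return list with mean baseline/follow-up volume (mm^3), their ranges,
#'   and mean +/- SD follow-up interval (years).
#' @export
cohort_descriptives <- function(cohort) {
  list(mean_volume_baseline = mean(cohort$vol_bl_mm3),
       range_volume_baseline = range(cohort$vol_bl_mm3),
       mean_volume_followup = mean(cohort$vol_fu_mm3),
       range_volume_followup = range(cohort$vol_fu_mm3),
       mean_fu_interval = mean(cohort$fu_interval_y),
       sd_fu_interval = sd(cohort$fu_interval_y),
       n = nrow(cohort))
}

#' Build pulsation-by-outcome 2x2 tables from per-examination results
#'
#' @param df `data.frame` with logical columns `swp_present`, `gvp_present`,
#'   `size_changed`.
#' @return named list of [contingency_2x2()] (`swp_vs_size_change`,
#'   `gvp_vs_size_change`).
#' @export
cohort_association_tables <- function(df) {
  stopifnot(all(c("swp_present", "gvp_present", "size_changed") %in% names(df)))
  mk <- function(exposure) {
    contingency_2x2(sum(exposure & df$size_changed),
                    sum(exposure & !df$size_changed),
                    sum(!exposure & df$size_changed),
                    sum(!exposure & !df$size_changed))
  }
  list(swp_vs_size_change = mk(df$swp_present),
       gvp_vs_size_change = mk(df$gvp_present))
}

#' Exact association statistics for a 2x2 table
#'
#' Convenience wrapper running the full exploratory battery on one table:
#' two-sided Fisher exact test, conditional-MLE odds ratio with exact CI,
#' and Newcombe risk difference.
#'
#' @param t a [contingency_2x2()].
#' @param level confidence level.
#' @return list with `fisher_p`, `odds_ratio`, `risk_difference`.
#' @export
association_statistics <- function(t, level = 0.95) {
  degenerate <- function(e) {
    list(point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         method = paste("degenerate:", conditionMessage(e)))
  }
  list(fisher_p = fisher_exact_two_sided(t),
       odds_ratio = tryCatch(conditional_or(t, level), error = degenerate),
       risk_difference = tryCatch(risk_difference(t, level), error = degenerate))
}
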