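#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every tunable of [simulate_cohort()]. Defaults
#' reproduce the population the pipeline is designed for: regularly
#' menstruating wearable users with mean cycle length 27.4 days (SD 2.2),
#' mean bleeding length 4.7 days, nightly resting heart rate (RHR) around
#' 59.7 BPM and RMSSD heart-rate variability around 60.4 ms, an RHR nadir
#' near cycle day 5 and peak near day 26 (RMSSD mirrored), a population
#' cardiovascular amplitude of about 2.7 BPM / 4.7 ms that declines with
#' age, small weekend and activity effects, and a contraceptive-pill cohort
#' whose within-cycle amplitude is strongly attenuated.
#'
#' @param n_participants Number of simulated participants.
#' @param prop_birth_control Fraction of participants assigned to the
#'   birth-control-pill cohort.
#' @param mean_cycle_len,sd_cycle_len Cycle length moments (days). Lengths are
#'   drawn as rounded Gaussians, resampled into \[21, 35\].
#' @param mean_bleed_len,sd_bleed_len Menstrual bleeding length moments
#'   (days), resampled into \[2, 7\].
#' @param rhr_baseline_mean,rhr_baseline_sd Between-participant baseline RHR
#'   distribution (BPM).
#' @param rmssd_baseline_mean,rmssd_baseline_sd Baseline RMSSD distribution
#'   (ms).
#' @param true_rhr_amp,true_rmssd_amp Population-mean injected peak-to-nadir
#'   amplitude for RHR (BPM) and RMSSD (ms) in the naturally cycling cohort.
#' @param sd_rhr_amp,sd_rmssd_amp Between-participant SD of the injected
#'   amplitude (BPM / ms); allows a realistic minority of participants with
#'   negative amplitude.
#' @param bc_attenuation Fractional attenuation of amplitude in the
#'   birth-control cohort (0.9 leaves 10% of the natural amplitude).
#' @param nadir_day,peak_day Anchor days of the within-cycle template.
#' @param age_slope_rhr_amp,age_slope_rmssd_amp Linear decline of injected
#'   amplitude with age (units per year, centred at age 35).
#' @param weekend_rhr_effect,weekend_rmssd_effect Additive weekend effects
#'   (BPM / ms) applied on Saturdays and Sundays.
#' @param kj_mean,kj_sd Daily prior-day energy expenditure distribution (kJ).
#' @param kj_slope_rhr,kj_slope_rmssd Linear effect of prior-day expenditure
#'   on each metric (units per kJ, centred at `kj_mean`).
#' @param noise_sd_rhr,noise_sd_rmssd Day-to-day Gaussian measurement noise
#'   SD (BPM / ms).
#' @param p_missing_day Probability a wear day is missing entirely.
#' @param p_outlier_day Probability a day carries an additive artifact spike
#'   of 4-8 noise SDs (random sign), sized to be caught by the 1.5 IQR rule.
#' @param n_cycles_range Integer (min, max) number of complete cycles per
#'   participant.
#' @param age_mean,age_sd,age_mean_bc,age_sd_bc Age distributions (years) for
#'   the naturally cycling and birth-control cohorts (ages truncated at 18).
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param rng_seed Integer seed; identical configurations give byte-identical
#'   simulated tables.
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_participants = 200,
                       prop_birth_control = 0,
                       mean_cycle_len = 27.4,
                       sd_cycle_len = 2.2,
                       mean_bleed_len = 4.7,
                       sd_bleed_len = 1.0,
                       rhr_baseline_mean = 59.7,
                       rhr_baseline_sd = 7.6,
                       rmssd_baseline_mean = 60.4,
                       rmssd_baseline_sd = 27.2,
                       true_rhr_amp = 2.7,
                       true_rmssd_amp = 4.7,
                       sd_rhr_amp = 1.8,
                       sd_rmssd_amp = 6.5,
                       bc_attenuation = 0.9,
                       nadir_day = 5,
                       peak_day = 26,
                       age_slope_rhr_amp = -0.04,
                       age_slope_rmssd_amp = -0.09,
                       weekend_rhr_effect = 0.9,
                       weekend_rmssd_effect = -1.8,
                       kj_mean = 7530,
                       kj_sd = 1004,
                       kj_slope_rhr = 2e-4,
                       kj_slope_rmssd = -4e-4,
                       noise_sd_rhr = 2.5,
                       noise_sd_rmssd = 8,
                       p_missing_day = 0.02,
                       p_outlier_day = 0.01,
                       n_cycles_range = c(3L, 5L),
                       age_mean = 35.5,
                       age_sd = 7.2,
                       age_mean_bc = 30.9,
                       age_sd_bc = 6.6,
                       bmi_mean = 24.6,
                       bmi_sd = 4.3,
                       rng_seed = 1L) {
  cf <- as.list(environment())

  sds <- c("sd_cycle_len", "sd_bleed_len", "rhr_baseline_sd",
           "rmssd_baseline_sd", "sd_rhr_amp", "sd_rmssd_amp", "kj_sd",
           "noise_sd_rhr", "noise_sd_rmssd", "age_sd", "age_sd_bc", "bmi_sd")
  for (nm in sds) {
    if (cf[[nm]] < 0) stop("`", nm, "` must be nonnegative", call. = FALSE)
  }
  probs <- c("prop_birth_control", "bc_attenuation", "p_missing_day",
             "p_outlier_day")
  for (nm in probs) {
    if (cf[[nm]] < 0 || cf[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  if (nadir_day >= peak_day) {
    stop("`nadir_day` must precede `peak_day`", call. = FALSE)
  }
  if (nadir_day < 1 || nadir_day > 14) {
    stop("`nadir_day` must lie within [1, 14] so every plausible cycle ",
         "length contains it", call. = FALSE)
  }
  if (peak_day > 35) {
    stop("`peak_day` must not exceed 35, the longest eligible cycle",
         call. = FALSE)
  }
  if (length(n_cycles_range) != 2 || any(n_cycles_range < 1) ||
      n_cycles_range[1] > n_cycles_range[2]) {
    stop("`n_cycles_range` must be an increasing pair of positive integers",
         call. = FALSE)
  }
  cf$n_cycles_range <- as.integer(n_cycles_range)
  cf$rng_seed <- as.integer(rng_seed)
  structure(cf, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participants (%.0f%% birth control), %d-%d cycles each\n",
              x$n_participants, 100 * x$prop_birth_control,
              x$n_cycles_range[1], x$n_cycles_range[2]))
  cat(sprintf("  cycle length %.1f (SD %.1f) d, bleeding %.1f (SD %.1f) d\n",
              x$mean_cycle_len, x$sd_cycle_len,
              x$mean_bleed_len, x$sd_bleed_len))
  cat(sprintf("  amplitude: RHR %.2f BPM, RMSSD %.2f ms; nadir day %d, peak day %d\n",
              x$true_rhr_amp, x$true_rmssd_amp, x$nadir_day, x$peak_day))
  cat(sprintf("  seed %d\n", x$rng_seed))
  invisible(x)
}
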