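# shared fixture builders; all synthetic, generated at test time

# a clean cohort: no noise, no missingness, no covariate effects, equal
# amplitude for everyone -- downstream results are then exact
clean_config <- function(n = 10, seed = 301, ...) {
  sim_config(
    n_participants = n,
    noise_sd_rhr = 0, noise_sd_rmssd = 0,
    sd_rhr_amp = 0, sd_rmssd_amp = 0,
    age_slope_rhr_amp = 0, age_slope_rmssd_amp = 0,
    weekend_rhr_effect = 0, weekend_rmssd_effect = 0,
    kj_slope_rhr = 0, kj_slope_rmssd = 0,
    p_missing_day = 0, p_outlier_day = 0,
    rng_seed = seed, ...
  )
}

# daily record tibble from explicit menstruation flags, one participant
flags_to_daily <- function(flags, id = "P1", start = as.Date("2022-03-01")) {
  tibble::tibble(
    participant_id = id,
    date = start + seq_along(flags) - 1,
    rhr_bpm = 60, rmssd_ms = 60, kj_prior_day = 7500,
    menstruating = as.integer(flags)
  )
}

# expected per-cycle amplitude for simulated truth: injected amplitude times
# the template's window contrast, evaluated directly on the generator's
# per-cycle anchor days (peak window = final 7 days, nadir window around the
# configured nadir day)
oracle_cycle_contrast <- function(cycle_len, config) {
  a <- template_anchor_days(cycle_len, config)
  tpl <- cycle_template(seq_len(cycle_len), cycle_len, a$nadir, a$peak)
  mean(tpl[(cycle_len - 6):cycle_len]) -
    mean(tpl[window_for_day(config$nadir_day, cycle_len)])
}
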