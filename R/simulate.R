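#' Simulate a wearable menstrual-cycle cohort with known ground truth
#'
#' Generates daily wearable records for a cohort of simulated participants
#' with a known within-cycle cardiovascular pattern, so every downstream
#' stage (delineation, filtering, normalization, population model, amplitude)
#' can be validated against ground truth. Each wear day's metric is
#'
#' \deqn{value = baseline + amp \cdot template(day) + weekend\ effect +
#'   activity\ effect + noise}
#'
#' with the RMSSD template sign-inverted relative to RHR (RHR nadirs early,
#' RMSSD peaks early). The per-participant amplitude `amp` combines the
#' population mean, a linear age trend, Gaussian between-participant
#' heterogeneity, and (for the birth-control cohort) multiplication by
#' `1 - bc_attenuation`. The menstruation flag is true for the first
#' `bleed_len` days of each cycle; a single onset day is appended after the
#' last cycle so that it can be closed by delineation. Missing wear days and
#' additive artifact spikes are injected at the configured rates.
#'
#' The within-cycle anchors are fixed cycle days; in cycles too short to
#' contain the configured peak day the peak anchor is clamped to the cycle's
#' last day. [template_anchor_days()] exposes this rule.
#'
#' @param config A [sim_config()] object. The generator seeds the RNG from
#'   `config$rng_seed`; identical configurations give identical output.
#' @return A list of four tibbles:
#' \describe{
#'   \item{daily}{one row per participant wear-day: `participant_id`, `date`,
#'     `rhr_bpm`, `rmssd_ms`, `kj_prior_day`, `menstruating` (0/1).}
#'   \item{participants}{`participant_id`, `age_years`, `bmi`, `cohort`
#'     (`"naturally_cycling"` or `"birth_control"`), `bc_start_date`,
#'     `bc_stop_date`.}
#'   \item{truth}{per-participant hidden parameters: cohort, effective
#'     `true_amp_rhr` / `true_amp_rmssd` (post-attenuation), baselines, age,
#'     BMI.}
#'   \item{truth_cycles}{the generator's cycle boundaries: `participant_id`,
#'     `cycle_index`, `start_date`, `length`, `bleed_length`.}
#' }
#' @examples
#' sim <- simulate_cohort(sim_config(n_participants = 5, rng_seed = 42))
#' head(sim$daily)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a `sim_config` object", call. = FALSE)
  }
  cf <- config
  set.seed(cf$rng_seed)
  n <- cf$n_participants

  id <- sprintf("P%05d", seq_len(n))
  n_bc <- round(cf$prop_birth_control * n)
  is_bc <- seq_len(n) <= n_bc
  cohort <- ifelse(is_bc, "birth_control", "naturally_cycling")

  age <- numeric(n)
  age[is_bc] <- rnorm_trunc(sum(is_bc), cf$age_mean_bc, cf$age_sd_bc, 18, 60)
  age[!is_bc] <- rnorm_trunc(sum(!is_bc), cf$age_mean, cf$age_sd, 18, 60)
  bmi <- rnorm_trunc(n, cf$bmi_mean, cf$bmi_sd, 15, 45)
  baseline_rhr <- rnorm_trunc(n, cf$rhr_baseline_mean, cf$rhr_baseline_sd,
                              35, 100)
  baseline_rmssd <- rnorm_trunc(n, cf$rmssd_baseline_mean,
                                cf$rmssd_baseline_sd, 10, 200)

  atten <- ifelse(is_bc, 1 - cf$bc_attenuation, 1)
  amp_rhr <- (cf$true_rhr_amp + cf$age_slope_rhr_amp * (age - 35) +
                rnorm(n, 0, cf$sd_rhr_amp)) * atten
  amp_rmssd <- (cf$true_rmssd_amp + cf$age_slope_rmssd_amp * (age - 35) +
                  rnorm(n, 0, cf$sd_rmssd_amp)) * atten

  per <- lapply(seq_len(n), function(i) {
    ks <- seq.int(cf$n_cycles_range[1], cf$n_cycles_range[2])
    k <- if (length(ks) == 1) ks else sample(ks, 1)
    lens <- round_trunc(k, cf$mean_cycle_len, cf$sd_cycle_len, 21, 35)
    bleeds <- round_trunc(k, cf$mean_bleed_len, cf$sd_bleed_len, 2, 7)
    start0 <- as.Date("2022-01-02") + sample(0:365, 1)
    starts <- start0 + c(0, cumsum(lens))[seq_len(k)]

    cyc <- tibble::tibble(
      participant_id = id[i],
      cycle_index = seq_len(k),
      start_date = starts,
      length = as.integer(lens),
      bleed_length = as.integer(bleeds)
    )

    day <- unlist(lapply(lens, seq_len), use.names = FALSE)
    cyc_of_day <- rep(seq_len(k), lens)
    date <- starts[cyc_of_day] + day - 1
    menstruating <- day <= bleeds[cyc_of_day]

    anchors <- template_anchor_days(lens, cf)
    tpl <- cycle_template_multi(day, lens[cyc_of_day],
                                anchors$nadir[cyc_of_day],
                                anchors$peak[cyc_of_day])

    # closing onset so the final cycle can be delineated
    date <- c(date, start0 + sum(lens))
    day <- c(day, 1L)
    tpl <- c(tpl, cycle_template_multi(1, lens[k], anchors$nadir[k],
                                       anchors$peak[k]))
    menstruating <- c(menstruating, TRUE)
    nd <- length(date)

    wk <- weekdays_weekend(date)
    kj <- rnorm_trunc(nd, cf$kj_mean, cf$kj_sd, 0, Inf)
    rhr <- baseline_rhr[i] + amp_rhr[i] * tpl +
      cf$weekend_rhr_effect * wk + cf$kj_slope_rhr * (kj - cf$kj_mean) +
      rnorm(nd, 0, cf$noise_sd_rhr)
    rmssd <- baseline_rmssd[i] - amp_rmssd[i] * tpl +
      cf$weekend_rmssd_effect * wk + cf$kj_slope_rmssd * (kj - cf$kj_mean) +
      rnorm(nd, 0, cf$noise_sd_rmssd)

    spike <- runif(nd) < cf$p_outlier_day
    ns <- sum(spike)
    if (ns > 0) {
      rhr[spike] <- rhr[spike] +
        sample(c(-1, 1), ns, replace = TRUE) * runif(ns, 4, 8) * cf$noise_sd_rhr
      rmssd[spike] <- rmssd[spike] +
        sample(c(-1, 1), ns, replace = TRUE) * runif(ns, 4, 8) * cf$noise_sd_rmssd
    }
    rhr <- pmax(rhr, 25)
    rmssd <- pmax(rmssd, 1)

    keep <- runif(nd) >= cf$p_missing_day
    daily <- tibble::tibble(
      participant_id = id[i],
      date = date,
      rhr_bpm = rhr,
      rmssd_ms = rmssd,
      kj_prior_day = kj,
      menstruating = as.integer(menstruating)
    )[keep, ]
    list(daily = daily, cycles = cyc)
  })

  daily <- dplyr::bind_rows(lapply(per, `[[`, "daily"))
  truth_cycles <- dplyr::bind_rows(lapply(per, `[[`, "cycles"))

  window_start <- min(daily$date)
  participants <- tibble::tibble(
    participant_id = id,
    age_years = age,
    bmi = bmi,
    cohort = cohort,
    bc_start_date = dplyr::if_else(is_bc, window_start - 30, as.Date(NA)),
    bc_stop_date = as.Date(NA)
  )
  truth <- tibble::tibble(
    participant_id = id,
    cohort = cohort,
    true_amp_rhr = amp_rhr,
    true_amp_rmssd = amp_rmssd,
    baseline_rhr = baseline_rhr,
    baseline_rmssd = baseline_rmssd,
    age = age,
    bmi = bmi
  )
  list(daily = daily, participants = participants, truth = truth,
       truth_cycles = truth_cycles)
}

#' Per-cycle template anchor days used by the generator
#'
#' Both anchors are fixed cycle days (the configured nadir and peak), except
#' that in cycles too short to contain the peak day the peak anchor is
#' clamped to the cycle's last day — the late-luteal peak cannot outlast the
#' cycle. With defaults (nadir 5, peak 26) most cycles peak exactly on day
#' 26 and longer cycles decline after it, so the pooled population curve
#' peaks at the configured day.
#'
#' @param cycle_len Vector of cycle lengths (days).
#' @param config A [sim_config()].
#' @return List with numeric vectors `nadir` and `peak`, one per cycle.
#' @export
template_anchor_days <- function(cycle_len, config) {
  peak <- pmin(config$peak_day, cycle_len)
  list(nadir = rep(config$nadir_day, length(cycle_len)), peak = peak)
}

# vectorized template over per-row cycle length and anchors
cycle_template_multi <- function(day, cycle_len, nadir_day, peak_day) {
  vapply(seq_along(day), function(j) {
    cycle_template(day[j], cycle_len[j], nadir_day[j], peak_day[j])
  }, numeric(1))
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

round_trunc <- function(n, mean, sd, lo, hi) {
  x <- round(rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- which(x < lo | x > hi)
  }
  x
}

weekdays_weekend <- function(date) {
  as.POSIXlt(date)$wday %in% c(0L, 6L)
}
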