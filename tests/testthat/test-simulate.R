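test_that("identical config and seed give identical tables", {
  cf <- sim_config(n_participants = 15, prop_birth_control = 0.4,
                   rng_seed = 99)
  s1 <- simulate_cohort(cf)
  s2 <- simulate_cohort(cf)
  expect_identical(s1$daily, s2$daily)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(sim_config(n_participants = 15,
                                   prop_birth_control = 0.4, rng_seed = 100))
  expect_false(identical(s1$daily, s3$daily))
})

test_that("noiseless cycles reproduce template-times-amplitude exactly", {
  cf <- clean_config(n = 6, seed = 302)
  sim <- simulate_cohort(cf)
  daily <- dplyr::inner_join(
    sim$daily,
    dplyr::inner_join(sim$truth_cycles, sim$truth, by = "participant_id"),
    by = "participant_id", relationship = "many-to-many")
  daily <- daily[daily$date >= daily$start_date &
                   daily$date < daily$start_date + daily$length, ]
  daily$day <- as.integer(daily$date - daily$start_date) + 1
  for (i in sample(nrow(daily), 50)) {
    r <- daily[i, ]
    a <- template_anchor_days(r$length, cf)
    tpl <- cycle_template(r$day, r$length, a$nadir, a$peak)
    expect_equal(r$rhr_bpm, r$baseline_rhr + r$true_amp_rhr * tpl,
                 tolerance = 1e-10)
    expect_equal(r$rmssd_ms, r$baseline_rmssd - r$true_amp_rmssd * tpl,
                 tolerance = 1e-10)
  }
})

test_that("full birth-control attenuation zeroes that cohort's amplitude", {
  cf <- sim_config(n_participants = 30, prop_birth_control = 0.5,
                   bc_attenuation = 1, rng_seed = 303)
  sim <- simulate_cohort(cf)
  bc <- sim$truth[sim$truth$cohort == "birth_control", ]
  nc <- sim$truth[sim$truth$cohort == "naturally_cycling", ]
  expect_true(all(bc$true_amp_rhr == 0))
  expect_true(all(bc$true_amp_rmssd == 0))
  expect_gt(mean(nc$true_amp_rhr), 1)
})

test_that("marginal moments match the configuration at n = 500", {
  cf <- sim_config(n_participants = 500, rng_seed = 304)
  sim <- simulate_cohort(cf)
  se <- function(x) sd(x) / sqrt(length(x))
  within3se <- function(x, target) abs(mean(x) - target) < 3 * se(x) + 1e-9
  expect_true(within3se(sim$truth$baseline_rhr, cf$rhr_baseline_mean))
  expect_true(within3se(sim$truth$baseline_rmssd, cf$rmssd_baseline_mean))
  expect_true(within3se(sim$truth$true_amp_rhr, cf$true_rhr_amp))
  lens <- sim$truth_cycles$length
  # rounding + truncation to [21, 35] barely moves the mean
  expect_true(abs(mean(lens) - cf$mean_cycle_len) < 3 * se(lens) + 0.1)
  bleeds <- sim$truth_cycles$bleed_length
  expect_true(abs(mean(bleeds) - cf$mean_bleed_len) < 3 * se(bleeds) + 0.1)
  expect_true(all(lens >= 21 & lens <= 35))
  expect_true(all(bleeds >= 2 & bleeds <= 7))
})

test_that("menstruation flags mark the first bleed_length days of each cycle", {
  cf <- clean_config(n = 4, seed = 305)
  sim <- simulate_cohort(cf)
  joined <- dplyr::inner_join(sim$daily, sim$truth_cycles,
                              by = "participant_id",
                              relationship = "many-to-many")
  joined <- joined[joined$date >= joined$start_date &
                     joined$date < joined$start_date + joined$length, ]
  day <- as.integer(joined$date - joined$start_date) + 1
  expect_identical(joined$menstruating == 1L, day <= joined$bleed_length)
})

test_that("missingness and outlier injection follow the configured rates", {
  cf <- sim_config(n_participants = 150, p_missing_day = 0.2,
                   p_outlier_day = 0, rng_seed = 306)
  sim <- simulate_cohort(cf)
  expected_days <- sum(sim$truth_cycles$length) + cf$n_participants
  frac <- nrow(sim$daily) / expected_days
  expect_gt(frac, 0.77)
  expect_lt(frac, 0.83)
})

test_that("cohort files round-trip through csv", {
  sim <- simulate_cohort(sim_config(n_participants = 4,
                                    prop_birth_control = 0.5, rng_seed = 307))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  daily <- read_daily(file.path(dir, "daily.csv"))
  expect_equal(as.data.frame(daily), as.data.frame(sim$daily))
  parts <- read_participants(file.path(dir, "participants.csv"))
  expect_equal(as.data.frame(parts), as.data.frame(sim$participants))
})
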