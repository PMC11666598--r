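make_cycles <- function(lengths, bleeds = rep(3, length(lengths)),
                        id = "P1", start = as.Date("2022-01-01")) {
  tibble::tibble(
    participant_id = id,
    cycle_index = seq_along(lengths),
    start_date = start + c(0, cumsum(utils::head(lengths, -1))),
    length = as.integer(lengths),
    bleed_length = as.integer(bleeds)
  )
}

full_wear_daily <- function(cycles) {
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    off <- 0:(cycles$length[i] - 1)
    tibble::tibble(
      participant_id = cycles$participant_id[i],
      date = cycles$start_date[i] + off,
      rhr_bpm = 60, rmssd_ms = 60, kj_prior_day = 7500,
      menstruating = as.integer(off < cycles$bleed_length[i])
    )
  })
  dplyr::bind_rows(rows)
}

test_that("cycle-length and bleeding rules exclude with the right codes", {
  cyc <- make_cycles(c(20, 27, 28, 36), bleeds = c(3, 8, 3, 3))
  filt <- apply_inclusion_filters(cyc, full_wear_daily(cyc))
  out <- filt$cycles
  expect_false(out$eligible[out$length == 20])
  expect_match(out$exclusion_codes[out$length == 20], "CYCLE_LEN")
  expect_false(out$eligible[out$bleed_length == 8])
  expect_match(out$exclusion_codes[out$bleed_length == 8], "BLEED_LEN")
  expect_false(out$eligible[out$length == 36])
  # the lone remaining 28-day cycle has no eligible neighbour
  expect_false(out$eligible[out$length == 28])
  expect_match(out$exclusion_codes[out$length == 28], "TOO_FEW_CONSECUTIVE")
})

test_that("boundary lengths 21 and 35 and exactly 95% pooled wear pass", {
  cyc <- make_cycles(c(21, 24))
  filt <- apply_inclusion_filters(cyc, full_wear_daily(cyc))
  expect_true(all(filt$cycles$eligible))   # boundary length 21 is inclusive

  cyc2 <- make_cycles(c(25, 35))           # 60 pooled days
  daily2 <- full_wear_daily(cyc2)
  drop <- daily2$date[c(3, 9, 50)]         # 57/60 = exactly 0.95: kept
  filt2 <- apply_inclusion_filters(cyc2, daily2[!daily2$date %in% drop, ])
  expect_true(all(filt2$cycles$eligible))
  expect_equal(sum(filt2$cycles$wear_fraction * filt2$cycles$length), 57)
  drop2 <- daily2$date[c(3, 9, 50, 51)]    # 56/60 < 0.95: excluded
  filt3 <- apply_inclusion_filters(cyc2, daily2[!daily2$date %in% drop2, ])
  expect_false(any(filt3$cycles$eligible))
  expect_match(filt3$cycles$exclusion_codes[1], "LOW_WEAR")
})

test_that("a lone eligible cycle fails the consecutive requirement", {
  cyc <- make_cycles(c(27))
  filt <- apply_inclusion_filters(cyc, full_wear_daily(cyc))
  expect_false(filt$cycles$eligible)
  expect_match(filt$cycles$exclusion_codes, "TOO_FEW_CONSECUTIVE")
})

test_that("relaxing thresholds never shrinks the eligible set", {
  sim <- simulate_cohort(sim_config(n_participants = 40, p_missing_day = 0.1,
                                    rng_seed = 321))
  cyc <- delineate_cycles(sim$daily)
  strict <- apply_inclusion_filters(cyc, sim$daily, min_wear = 0.95)
  relaxed <- apply_inclusion_filters(cyc, sim$daily, min_wear = 0.85,
                                     min_cycle_len = 20, max_cycle_len = 36,
                                     max_bleed_len = 8)
  key <- function(x) paste(x$participant_id, x$cycle_index)
  elig_strict <- key(strict$cycles[strict$cycles$eligible, ])
  elig_relaxed <- key(relaxed$cycles[relaxed$cycles$eligible, ])
  expect_true(all(elig_strict %in% elig_relaxed))
})

test_that("eligibility matches a brute-force reimplementation of the rules", {
  sim <- simulate_cohort(sim_config(n_participants = 40, p_missing_day = 0.2,
                                    rng_seed = 322))
  cyc <- delineate_cycles(sim$daily)
  filt <- apply_inclusion_filters(cyc, sim$daily)

  # independent oracle: literal loops over each participant's cycles
  oracle <- logical(nrow(cyc))
  cyc_split <- split(seq_len(nrow(cyc)), cyc$participant_id)
  for (rows in cyc_split) {
    cc <- cyc[rows, ]
    ok <- cc$length >= 21 & cc$length <= 35 & cc$bleed_length <= 7
    wear <- integer(nrow(cc))
    for (i in seq_len(nrow(cc))) {
      days <- cc$start_date[i] + 0:(cc$length[i] - 1)
      sub <- sim$daily[sim$daily$participant_id == cc$participant_id[i], ]
      wear[i] <- sum(sub$date %in% days & !is.na(sub$rhr_bpm))
    }
    run_id <- cumsum(!ok | c(TRUE, diff(cc$cycle_index) != 1))
    for (r in unique(run_id)) {
      in_run <- run_id == r & ok
      if (sum(in_run) >= 2 &&
          sum(wear[in_run]) / sum(cc$length[in_run]) >= 0.95) {
        oracle[rows[in_run]] <- TRUE
      }
    }
  }
  expect_equal(filt$cycles$eligible, oracle)
})

test_that("the exclusion ledger is exhaustive and consistent", {
  sim <- simulate_cohort(sim_config(n_participants = 40, p_missing_day = 0.15,
                                    rng_seed = 323))
  cyc <- delineate_cycles(sim$daily)
  led <- apply_inclusion_filters(cyc, sim$daily)$ledger
  assessed <- led$cycles[led$rule == "ASSESSED"]
  included <- led$cycles[led$rule == "INCLUDED"]
  removed <- -sum(led$cycles[!led$rule %in% c("ASSESSED", "INCLUDED")])
  expect_equal(assessed, included + removed)
  expect_equal(assessed, nrow(cyc))
})

test_that("cycles overlapping a pill interval are assigned to birth control", {
  cyc <- make_cycles(c(28, 28, 28))
  meta <- tibble::tibble(participant_id = "P1",
                         bc_start_date = as.Date("2022-02-10"),
                         bc_stop_date = as.Date(NA))
  out <- assign_cohort(cyc, meta)
  expect_equal(out$cohort, c("naturally_cycling", "birth_control",
                             "birth_control"))
  meta_none <- tibble::tibble(participant_id = "P1",
                              bc_start_date = as.Date(NA),
                              bc_stop_date = as.Date(NA))
  expect_true(all(assign_cohort(cyc, meta_none)$cohort == "naturally_cycling"))
})
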