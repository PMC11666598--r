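# shared noiseless fit: the day smooth must reproduce the injected curve
noiseless_proc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cf <- clean_config(n = 50, seed = 341, sd_cycle_len = 0)
      sim <- simulate_cohort(cf)
      cache <<- list(cf = cf, sim = sim,
                     proc = process_cohort(sim$daily, sim$participants))
    }
    cache
  }
})

test_that("noiseless fit reproduces the injected day curve and extrema", {
  nl <- noiseless_proc()
  # near-saturated basis (cycles share 27 distinct days): the check is
  # fidelity of the fit to the injected curve, including its steep start
  fit <- fit_population(nl$proc$offsets, "rhr", basis_dim = 25)
  pd <- partial_dependence_day(fit, step = 0.01)
  ex <- locate_extrema(pd)
  expect_equal(ex$nadir_day_nearest, 5L)
  expect_equal(ex$peak_day_nearest, 26L)

  # all cycles share length 27 here, so the injected curve is the template
  # itself, centred like the offsets; compare on integer days
  L <- nl$proc$offsets$cycle_len[1]
  amp <- nl$sim$truth$true_amp_rhr[1]
  a <- template_anchor_days(L, nl$cf)
  tpl <- cycle_template(1:L, L, a$nadir, a$peak)
  injected <- amp * (tpl - mean(tpl))
  fitted <- pd$estimate[match(1:L, round(pd$day, 6))]
  expect_lt(max(abs(fitted - mean(fitted) - (injected - mean(injected)))),
            0.1)
})

test_that("participant-constant shifts are absorbed by the random intercepts", {
  nl <- noiseless_proc()
  off <- nl$proc$offsets
  set.seed(42)
  shifts <- stats::setNames(rnorm(50, 0, 3),
                            unique(off$participant_id))
  off_shift <- off
  off_shift$offset <- off$offset + shifts[off$participant_id]
  f0 <- fit_population(off, "rhr")
  f1 <- fit_population(off_shift, "rhr")
  pd0 <- partial_dependence_day(f0, step = 0.1)
  pd1 <- partial_dependence_day(f1, step = 0.1)
  expect_lt(max(abs(pd0$estimate - pd1$estimate)), 0.05)
})

test_that("fitted random intercepts are near zero on centred synthetic data", {
  sim <- simulate_cohort(sim_config(n_participants = 60, rng_seed = 342))
  proc <- process_cohort(sim$daily, sim$participants)
  fit <- fit_population(proc$offsets, "rhr")
  b <- stats::coef(fit$gam)
  se <- sqrt(diag(fit$gam$Vp))
  idx <- grep("s\\(pid\\)", names(b))
  expect_gt(mean(abs(b[idx]) < 3 * se[idx]), 0.95)
})

test_that("weekend and covariate effects are recovered by the adjusted fit", {
  cf <- sim_config(n_participants = 120, rng_seed = 343)
  sim <- simulate_cohort(cf)
  proc <- process_cohort(sim$daily, sim$participants)
  fit <- fit_population(proc$offsets, "rhr", adjusted = TRUE)
  smry <- population_summary(fit)
  wk <- smry[smry$term == "weekendTRUE", ]
  expect_lt(abs(wk$estimate - cf$weekend_rhr_effect),
            3 * (wk$estimate - wk$ci_lower) / 1.96)
  expect_lt(wk$p_value, 0.001)
  # unadjusted day curve agrees with the adjusted one within the band
  f0 <- fit_population(proc$offsets, "rhr")
  pd0 <- partial_dependence_day(f0, step = 0.1)
  pd1 <- partial_dependence_day(fit, step = 0.1)
  cover <- mean(pd1$estimate >= pd0$ci_lower & pd1$estimate <= pd0$ci_upper)
  expect_gt(cover, 0.9)
})

test_that("flat curves are rejected and fine grids are stable", {
  pd_flat <- tibble::tibble(day = seq(1, 28, 0.1),
                            estimate = 0,
                            ci_lower = -0.1, ci_upper = 0.1)
  expect_error(locate_extrema(pd_flat), "no cycle structure")

  nl <- noiseless_proc()
  fit <- fit_population(nl$proc$offsets, "rhr")
  e1 <- locate_extrema(partial_dependence_day(fit, step = 0.02))
  e2 <- locate_extrema(partial_dependence_day(fit, step = 0.01))
  expect_lt(abs(e1$nadir_day - e2$nadir_day), 0.02 + 1e-9)
  expect_lt(abs(e1$peak_day - e2$peak_day), 0.02 + 1e-9)
})

test_that("extrema on an exact cosine grid are read off correctly", {
  g <- seq(1, 28, by = 0.01)
  pd <- tibble::tibble(day = g, estimate = -cos(2 * pi * (g - 5) / 28),
                       ci_lower = NA_real_, ci_upper = NA_real_)
  ex <- locate_extrema(pd)
  expect_equal(ex$nadir_day, 5)
  expect_equal(ex$nadir_day_nearest, 5L)
  expect_equal(ex$peak_day, 19)   # antiphase of a plain cosine
  # half-day ties round toward the earlier day
  pd2 <- tibble::tibble(day = c(1, 4.5, 9), estimate = c(0, 1, -1),
                        ci_lower = NA_real_, ci_upper = NA_real_)
  ex2 <- locate_extrema(pd2)
  expect_equal(ex2$peak_day_nearest, 4L)
})

test_that("doubling the basis dimension moves extrema by less than half a day", {
  sim <- simulate_cohort(sim_config(n_participants = 120, rng_seed = 344))
  proc <- process_cohort(sim$daily, sim$participants)
  lens <- unique(proc$offsets[proc$offsets$metric == "rhr",
                              c("participant_id", "cycle_index",
                                "cycle_len")])$cycle_len
  dmax <- as.numeric(quantile(lens, 0.95))
  e10 <- locate_extrema(partial_dependence_day(
    fit_population(proc$offsets, "rhr", basis_dim = 10),
    step = 0.05, day_max = dmax))
  e20 <- locate_extrema(partial_dependence_day(
    fit_population(proc$offsets, "rhr", basis_dim = 20),
    step = 0.05, day_max = dmax))
  expect_lt(abs(e10$nadir_day - e20$nadir_day), 0.5)
  expect_lt(abs(e10$peak_day - e20$peak_day), 0.5)
})

test_that("RHR and RMSSD extrema are antiphase on default synthetic data", {
  sim <- simulate_cohort(sim_config(n_participants = 150, rng_seed = 345))
  res <- run_amplitude_analysis(sim$daily, sim$participants, grid_step = 0.05)
  expect_lt(abs(res$rhr$extrema$nadir_day - res$rmssd$extrema$peak_day), 1.5)
  expect_lt(abs(res$rhr$extrema$peak_day - res$rmssd$extrema$nadir_day), 1.5)
})

test_that("a single participant fits without the random effect, with warning", {
  sim <- simulate_cohort(sim_config(n_participants = 1, rng_seed = 346))
  proc <- process_cohort(sim$daily, sim$participants)
  expect_warning(fit <- fit_population(proc$offsets, "rhr"),
                 "single participant")
  expect_s3_class(fit, "population_fit")
})
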