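#' Run the processing pipeline: delineation, filtering, offsets
#'
#' Convenience wrapper chaining [delineate_cycles()],
#' [apply_inclusion_filters()] and [cycle_offsets()] on a cohort's daily
#' records, keeping only eligible cycles.
#'
#' @param daily Daily records tibble.
#' @param participants Optional participant metadata.
#' @param ... Filter thresholds passed to [apply_inclusion_filters()].
#' @return List with `cycles` (all delineated cycles with eligibility),
#'   `ledger` (exclusion accounting) and `offsets` (long table for the
#'   eligible cycles).
#' @export
process_cohort <- function(daily, participants = NULL, ...) {
  cycles <- delineate_cycles(daily)
  filt <- apply_inclusion_filters(cycles, daily, ...)
  elig <- filt$cycles[filt$cycles$eligible, ]
  if (nrow(elig) == 0) {
    stop("no eligible cycles after filtering", call. = FALSE)
  }
  offsets <- cycle_offsets(daily, elig, participants)
  list(cycles = filt$cycles, ledger = filt$ledger, offsets = offsets)
}

#' Run the full amplitude analysis on a cohort
#'
#' End-to-end convenience wrapper: processes the cohort, fits the
#' (unadjusted) population model per metric, locates the population extrema,
#' and computes per-cycle and per-participant amplitudes using the
#' nearest-day anchors.
#'
#' The extrema search is restricted to well-supported cycle days (up to the
#' 95th percentile of eligible cycle length): later days are reached only by
#' the few longest cycles, and the wide-uncertainty tail of the smooth there
#' should not define the population anchors.
#'
#' @param daily Daily records tibble.
#' @param participants Optional participant metadata.
#' @param metrics Metrics to analyse (default both).
#' @param basis_dim,method Passed to [fit_population()].
#' @param grid_step Passed to [partial_dependence_day()].
#' @param min_days Passed to [compute_amplitudes()].
#' @param support_quantile Quantile of eligible cycle length bounding the
#'   extrema search (default 0.95).
#' @param ... Filter thresholds passed to [apply_inclusion_filters()].
#' @return List with `processed` (see [process_cohort()]) and, per metric,
#'   `fit`, `partial_dependence`, `extrema`, `cycle_amplitudes`,
#'   `participant_amplitudes`, `summary`.
#' @export
run_amplitude_analysis <- function(daily, participants = NULL,
                                   metrics = c("rhr", "rmssd"),
                                   basis_dim = 10, method = "GCV.Cp",
                                   grid_step = 0.01, min_days = 4,
                                   support_quantile = 0.95, ...) {
  proc <- process_cohort(daily, participants, ...)
  lens <- dplyr::distinct(proc$offsets, .data$participant_id,
                          .data$cycle_index, .data$cycle_len)$cycle_len
  day_max <- as.numeric(quantile(lens, support_quantile))
  res <- list(processed = proc)
  for (m in metrics) {
    fit <- fit_population(proc$offsets, metric = m, adjusted = FALSE,
                          basis_dim = basis_dim, method = method)
    pd <- partial_dependence_day(fit, step = grid_step, day_max = day_max)
    ex <- locate_extrema(pd)
    ca <- compute_amplitudes(proc$offsets, metric = m,
                             peak_day = ex$peak_day_nearest,
                             nadir_day = ex$nadir_day_nearest,
                             min_days = min_days)
    pa <- participant_amplitudes(ca)
    res[[m]] <- list(fit = fit, partial_dependence = pd, extrema = ex,
                     cycle_amplitudes = ca, participant_amplitudes = pa,
                     summary = amplitude_summary(pa))
  }
  res
}
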