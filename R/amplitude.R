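#' Seven-day window centered on an anchor day
#'
#' Returns the inclusive 7-day range of cycle days centered on `anchor_day`,
#' shifted inward when the anchor lies fewer than 3 days from the beginning
#' or end of the cycle so that a full 7-day window is always available:
#' anchors at day 3 or earlier give days 1-7, anchors within 2 days of the
#' cycle end (or beyond it) give the final 7 days.
#'
#' @param anchor_day Integer cycle day the window is centered on.
#' @param cycle_len Cycle length in days (must be at least 7).
#' @return Integer vector of 7 consecutive cycle days.
#' @examples
#' window_for_day(5, 28)   # days 2-8
#' window_for_day(26, 27)  # final 7 days, 21-27
#' @export
window_for_day <- function(anchor_day, cycle_len) {
  if (cycle_len < 7) stop("`cycle_len` must be at least 7", call. = FALSE)
  if (anchor_day < 1) stop("`anchor_day` must be >= 1", call. = FALSE)
  start <- max(1, min(anchor_day - 3, cycle_len - 6))
  seq.int(start, start + 6)
}

#' Cardiovascular amplitude of a single cycle
#'
#' The cycle cardiovascular amplitude is the mean offset over the 7-day
#' window around the population-expected peak minus the mean offset over the
#' 7-day window around the population-expected nadir. For RHR the peak
#' window is the late-cycle window and the nadir window the early one; for
#' RMSSD the roles swap (its population peak falls near day 5), so a single
#' peak-minus-nadir convention covers both metrics. When an anchor is
#' flagged as lying at the cycle end (see [compute_amplitudes()]), its
#' window is the cycle's own final 7 days regardless of length. A window
#' with fewer than `min_days` non-missing offsets makes the amplitude
#' undefined (NA).
#'
#' @param offsets Numeric vector of daily offsets indexed by cycle day
#'   (position 1 = cycle day 1, NA on missing/outlier days); length
#'   `cycle_len`.
#' @param peak_day,nadir_day Integer anchor days from the population model.
#' @param cycle_len Cycle length in days (default `length(offsets)`).
#' @param min_days Minimum non-missing offsets per window (default 4).
#' @param peak_at_end,nadir_at_end Anchor this window to the cycle's final 7
#'   days (default FALSE).
#' @return One-row tibble: `amplitude`, `peak_mean`, `nadir_mean`,
#'   `n_peak_days`, `n_nadir_days`, `overlap` (TRUE when the two windows
#'   share days, possible in short cycles).
#' @examples
#' off <- rep(NA_real_, 28); off[2:8] <- -1.36; off[22:28] <- 1.37
#' cycle_amplitude(off, peak_day = 26, nadir_day = 5, min_days = 4,
#'                 peak_at_end = TRUE)$amplitude  # 2.73
#' @export
cycle_amplitude <- function(offsets, peak_day, nadir_day,
                            cycle_len = length(offsets), min_days = 4,
                            peak_at_end = FALSE, nadir_at_end = FALSE) {
  if (length(offsets) < cycle_len) {
    offsets <- c(offsets, rep(NA_real_, cycle_len - length(offsets)))
  }
  pw <- if (peak_at_end) seq.int(cycle_len - 6, cycle_len) else
    window_for_day(peak_day, cycle_len)
  nw <- if (nadir_at_end) seq.int(cycle_len - 6, cycle_len) else
    window_for_day(nadir_day, cycle_len)
  pv <- offsets[pw]
  nv <- offsets[nw]
  n_p <- sum(!is.na(pv))
  n_n <- sum(!is.na(nv))
  amp <- if (n_p >= min_days && n_n >= min_days) {
    mean(pv, na.rm = TRUE) - mean(nv, na.rm = TRUE)
  } else NA_real_
  tibble::tibble(
    amplitude = amp,
    peak_mean = if (n_p > 0) mean(pv, na.rm = TRUE) else NA_real_,
    nadir_mean = if (n_n > 0) mean(nv, na.rm = TRUE) else NA_real_,
    n_peak_days = n_p, n_nadir_days = n_n,
    overlap = length(intersect(pw, nw)) > 0
  )
}

#' Per-cycle cardiovascular amplitudes for a cohort
#'
#' Applies [cycle_amplitude()] to every participant-cycle in an offsets
#' table for one metric. An anchor within 3 days of the population mean
#' cycle end is anchored to each individual cycle's final 7 days (the
#' published convention for the late-luteal window); the other anchor uses
#' its fixed population day.
#'
#' @param offsets Long offsets table from [cycle_offsets()].
#' @param metric `"rhr"` or `"rmssd"`.
#' @param peak_day,nadir_day Integer anchor days, typically
#'   `locate_extrema()$peak_day_nearest` / `$nadir_day_nearest`.
#' @param min_days Minimum non-missing offsets per window (default 4).
#' @param mean_cycle_len Population mean cycle length used for the
#'   end-anchoring rule; default: mean length of the cycles in `offsets`.
#' @return Tibble with one row per participant-cycle: `participant_id`,
#'   `cycle_index`, `cycle_len`, amplitude columns of [cycle_amplitude()].
#' @export
compute_amplitudes <- function(offsets, metric = c("rhr", "rmssd"),
                               peak_day, nadir_day, min_days = 4,
                               mean_cycle_len = NULL) {
  metric <- match.arg(metric)
  d <- offsets[offsets$metric == metric, ]
  if (nrow(d) == 0) stop("no offset rows for metric ", metric, call. = FALSE)
  if (is.null(mean_cycle_len)) {
    lens <- dplyr::distinct(d, .data$participant_id, .data$cycle_index,
                            .data$cycle_len)
    mean_cycle_len <- mean(lens$cycle_len)
  }
  peak_at_end <- peak_day >= mean_cycle_len - 2
  nadir_at_end <- nadir_day >= mean_cycle_len - 2

  d |>
    dplyr::group_by(.data$participant_id, .data$cycle_index,
                    .data$cycle_len) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      off <- rep(NA_real_, key$cycle_len)
      off[df$day] <- df$offset
      cycle_amplitude(off, peak_day = peak_day, nadir_day = nadir_day,
                      cycle_len = key$cycle_len, min_days = min_days,
                      peak_at_end = peak_at_end, nadir_at_end = nadir_at_end)
    }) |>
    dplyr::ungroup()
}

#' Participant-level amplitude (RHR_amp / RMSSD_amp)
#'
#' A participant's cardiovascular amplitude is the arithmetic mean of their
#' defined cycle amplitudes. Participants with no defined cycle amplitude
#' are dropped (with a message).
#'
#' @param cycle_amps Per-cycle tibble from [compute_amplitudes()].
#' @return Tibble `participant_id`, `participant_amp`, `n_cycles_used`.
#' @export
participant_amplitudes <- function(cycle_amps) {
  out <- cycle_amps |>
    dplyr::filter(!is.na(.data$amplitude)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(participant_amp = mean(.data$amplitude),
                     n_cycles_used = dplyr::n(), .groups = "drop")
  n_dropped <- length(setdiff(unique(cycle_amps$participant_id),
                              out$participant_id))
  if (n_dropped > 0) {
    message(n_dropped,
            " participant(s) had no defined cycle amplitude and were dropped")
  }
  out
}

#' Cohort summary of participant amplitudes
#'
#' @param participant_amps Tibble from [participant_amplitudes()].
#' @return One-row tibble: `n`, `mean`, `sd`, `pct_positive` (percentage of
#'   participants with a positive amplitude).
#' @export
amplitude_summary <- function(participant_amps) {
  tibble::tibble(
    n = nrow(participant_amps),
    mean = mean(participant_amps$participant_amp),
    sd = sd(participant_amps$participant_amp),
    pct_positive = 100 * mean(participant_amps$participant_amp > 0)
  )
}
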