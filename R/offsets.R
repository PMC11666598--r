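#' Offsets from the outlier-free cycle mean
#'
#' Normalizes one participant-cycle's daily metric series to within-cycle
#' offsets in absolute units: each day's offset is its value minus the mean
#' of the cycle's surviving (non-missing, non-outlier by the 1.5 IQR rule)
#' values. Outlier days carry no offset (NA) and are treated as missing
#' downstream. By construction the surviving offsets sum to zero.
#'
#' @param values Numeric vector of daily values for one participant-cycle
#'   (NA = missing day).
#' @inheritParams remove_outliers_iqr
#' @return List with `offset` (numeric vector, NA on missing/outlier days),
#'   `keep` (logical), `fences`, and `cycle_mean`.
#' @examples
#' compute_offsets(c(60, 62, 58))$offset  # 0, +2, -2
#' @export
compute_offsets <- function(values, k = 1.5, min_n = 4) {
  out <- remove_outliers_iqr(values, k = k, min_n = min_n)
  if (!any(out$keep)) {
    return(list(offset = rep(NA_real_, length(values)), keep = out$keep,
                fences = out$fences, cycle_mean = NA_real_))
  }
  m <- mean(values[out$keep])
  offset <- ifelse(out$keep, values - m, NA_real_)
  list(offset = offset, keep = out$keep, fences = out$fences, cycle_mean = m)
}

#' Build the long offsets table for a set of cycles
#'
#' Expands each cycle to its day grid (day 1 = bleeding onset), joins the
#' daily wearable records, applies the within-cycle IQR outlier rule and
#' offset normalization separately per metric, and attaches participant
#' covariates. This is the modelling table consumed by [fit_population()]
#' and [compute_amplitudes()].
#'
#' @param daily Daily records tibble (`participant_id`, `date`, `rhr_bpm`,
#'   `rmssd_ms`, `kj_prior_day`, `menstruating`).
#' @param cycles Cycle tibble from [delineate_cycles()] (typically filtered by
#'   [apply_inclusion_filters()] first).
#' @param participants Optional participant metadata (`participant_id`,
#'   `age_years`, `bmi`, `cohort`) to join onto the table.
#' @inheritParams remove_outliers_iqr
#' @return Long tibble with one row per cycle-day per metric:
#'   `participant_id`, `cycle_index`, `cycle_len`, `day`, `date`, `metric`
#'   (`"rhr"`/`"rmssd"`), `value`, `offset` (NA on missing/outlier days),
#'   `outlier`, `weekend`, `kj`, and, when metadata are supplied, `age`,
#'   `bmi`, `cohort`.
#' @export
cycle_offsets <- function(daily, cycles, participants = NULL,
                          k = 1.5, min_n = 4) {
  if (nrow(cycles) == 0) {
    stop("no cycles to process", call. = FALSE)
  }
  grid <- cycles |>
    dplyr::select("participant_id", "cycle_index", "start_date", "length") |>
    dplyr::rowwise() |>
    dplyr::mutate(day = list(seq_len(.data$length))) |>
    dplyr::ungroup() |>
    tidyr::unnest("day") |>
    dplyr::mutate(date = .data$start_date + .data$day - 1,
                  cycle_len = .data$length) |>
    dplyr::select(-"start_date", -"length")

  long <- grid |>
    dplyr::left_join(daily, by = c("participant_id", "date")) |>
    dplyr::mutate(weekend = weekdays_weekend(.data$date),
                  kj = .data$kj_prior_day) |>
    tidyr::pivot_longer(cols = c("rhr_bpm", "rmssd_ms"), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = ifelse(.data$metric == "rhr_bpm", "rhr", "rmssd"))

  long <- long |>
    dplyr::group_by(.data$participant_id, .data$cycle_index, .data$metric) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      off <- compute_offsets(df$value, k = k, min_n = min_n)
      df$offset <- off$offset
      df$outlier <- !is.na(df$value) & !off$keep
      df
    }) |>
    dplyr::ungroup()

  if (!is.null(participants)) {
    meta <- participants |>
      dplyr::select("participant_id",
                    dplyr::any_of(c("age_years", "bmi", "cohort"))) |>
      dplyr::rename(dplyr::any_of(c(age = "age_years")))
    long <- dplyr::left_join(long, meta, by = "participant_id")
  }
  long |>
    dplyr::select(dplyr::any_of(c(
      "participant_id", "cycle_index", "cycle_len", "day", "date", "metric",
      "value", "offset", "outlier", "weekend", "kj", "age", "bmi", "cohort"
    )))
}
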