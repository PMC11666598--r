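#' Apply cohort eligibility filters to delineated cycles
#'
#' Implements the study's inclusion rules: a cycle is eligible iff its length
#' lies in \[`min_cycle_len`, `max_cycle_len`\], its bleeding lasts at most
#' `max_bleed_len` days, and it belongs to a maximal run of at least
#' `min_consecutive` back-to-back cycles (no intervening ineligible cycle)
#' whose pooled wear fraction — days with a non-missing RHR value divided by
#' total cycle days, pooled over the run — is at least `min_wear`. The wear
#' threshold is inclusive (exactly 95% wear passes). An exclusion ledger
#' reports, in order of application, how many cycles and participants each
#' rule removed, with removals + included = assessed.
#'
#' @param cycles Tibble from [delineate_cycles()].
#' @param daily Daily records tibble (used for wear: non-missing `rhr_bpm`).
#' @param min_cycle_len,max_cycle_len Eligible cycle-length range in days
#'   (defaults 21, 35).
#' @param max_bleed_len Maximum bleeding length in days (default 7).
#' @param min_wear Minimum pooled wear fraction (default 0.95, inclusive).
#' @param min_consecutive Minimum run of consecutive eligible cycles
#'   (default 2).
#' @return List with `cycles` (input plus `wear_fraction`, `eligible`,
#'   `exclusion_codes`) and `ledger` (tibble of rule, cycles and participants
#'   removed, ordered as applied: CYCLE_LEN, BLEED_LEN, CONSECUTIVE_WEAR).
#' @export
apply_inclusion_filters <- function(cycles, daily,
                                    min_cycle_len = 21, max_cycle_len = 35,
                                    max_bleed_len = 7, min_wear = 0.95,
                                    min_consecutive = 2) {
  if (nrow(cycles) == 0) {
    return(list(cycles = cycles, ledger = tibble::tibble(
      rule = character(), cycles_removed = integer(),
      participants_removed = integer())))
  }

  wear_days <- daily |>
    dplyr::filter(!is.na(.data$rhr_bpm)) |>
    dplyr::distinct(.data$participant_id, .data$date)

  wear_counts <- wear_days |>
    dplyr::inner_join(
      dplyr::select(cycles, "participant_id", "cycle_index", "start_date",
                    "length"),
      by = "participant_id", relationship = "many-to-many") |>
    dplyr::filter(.data$date >= .data$start_date,
                  .data$date < .data$start_date + .data$length) |>
    dplyr::count(.data$participant_id, .data$cycle_index, name = "wear_days")

  cyc <- cycles |>
    dplyr::arrange(.data$participant_id, .data$cycle_index) |>
    dplyr::left_join(wear_counts, by = c("participant_id", "cycle_index")) |>
    dplyr::mutate(wear_days = dplyr::coalesce(.data$wear_days, 0L)) |>
    dplyr::mutate(
      wear_fraction = .data$wear_days / .data$length,
      len_ok = .data$length >= min_cycle_len & .data$length <= max_cycle_len,
      bleed_ok = .data$bleed_length <= max_bleed_len
    )

  # maximal runs of consecutive length/bleed-eligible cycles, per participant
  cyc <- cyc |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      rule_ok = .data$len_ok & .data$bleed_ok,
      # a run continues only through contiguous rule-eligible cycles
      run_break = !(.data$rule_ok &
                      dplyr::lag(.data$rule_ok, default = FALSE) &
                      c(FALSE, diff(.data$cycle_index) == 1L)),
      run_id = cumsum(.data$run_break)
    ) |>
    dplyr::group_by(.data$participant_id, .data$run_id) |>
    dplyr::mutate(
      run_n = ifelse(.data$rule_ok, dplyr::n(), 0L),
      run_wear = sum(.data$wear_days) / sum(.data$length)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      consec_ok = .data$rule_ok & .data$run_n >= min_consecutive,
      wear_ok = .data$rule_ok & .data$run_wear >= min_wear,
      eligible = .data$rule_ok & .data$consec_ok & .data$wear_ok,
      exclusion_codes = mapply(function(l, b, c, w) {
        paste(c(if (!l) "CYCLE_LEN", if (!b) "BLEED_LEN",
                if (l && b && !c) "TOO_FEW_CONSECUTIVE",
                if (l && b && c && !w) "LOW_WEAR"), collapse = ",")
      }, .data$len_ok, .data$bleed_ok, .data$consec_ok, .data$wear_ok)
    ) |>
    dplyr::select(-"run_break", -"run_id", -"rule_ok", -"wear_days")

  ledger <- exclusion_ledger(cyc)
  list(cycles = cyc, ledger = ledger)
}

# sequential rule accounting: each cycle/participant is counted at the first
# rule that removes it, mirroring a participant-flow diagram
exclusion_ledger <- function(cyc) {
  stages <- list(
    CYCLE_LEN = !cyc$len_ok,
    BLEED_LEN = cyc$bleed_ok == FALSE,
    CONSECUTIVE_WEAR = !cyc$consec_ok | !cyc$wear_ok
  )
  remaining <- rep(TRUE, nrow(cyc))
  participants_left <- function(m) length(unique(cyc$participant_id[m]))
  rows <- list(tibble::tibble(
    rule = "ASSESSED",
    cycles = sum(remaining),
    participants = participants_left(remaining)
  ))
  for (nm in names(stages)) {
    removed <- remaining & stages[[nm]]
    before_p <- participants_left(remaining)
    remaining <- remaining & !stages[[nm]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      rule = nm,
      cycles = -sum(removed),
      participants = -(before_p - participants_left(remaining))
    )
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    rule = "INCLUDED",
    cycles = sum(remaining),
    participants = participants_left(remaining)
  )
  dplyr::bind_rows(rows)
}

#' Assign a cohort to each participant-cycle from birth-control intervals
#'
#' A cycle belongs to the birth-control cohort when it overlaps the
#' participant's reported pill interval (`bc_start_date` to `bc_stop_date`,
#' an open stop date meaning ongoing use); otherwise the participant is
#' naturally cycling for that cycle. Participants may therefore contribute
#' cycles to both cohorts at different times.
#'
#' @param cycles Cycle tibble with `participant_id`, `start_date`, `length`.
#' @param participants Metadata with `participant_id`, `bc_start_date`,
#'   `bc_stop_date` (NA when no hormonal birth control was reported).
#' @return `cycles` with a `cohort` column (`"birth_control"` or
#'   `"naturally_cycling"`).
#' @export
assign_cohort <- function(cycles, participants) {
  meta <- participants |>
    dplyr::select("participant_id", "bc_start_date", "bc_stop_date")
  cycles |>
    dplyr::left_join(meta, by = "participant_id") |>
    dplyr::mutate(
      cycle_end = .data$start_date + .data$length - 1,
      bc_stop = dplyr::coalesce(.data$bc_stop_date, as.Date("9999-12-31")),
      cohort = dplyr::if_else(
        !is.na(.data$bc_start_date) &
          .data$start_date <= .data$bc_stop &
          .data$cycle_end >= .data$bc_start_date,
        "birth_control", "naturally_cycling")
    ) |>
    dplyr::select(-"cycle_end", -"bc_stop", -"bc_start_date",
                  -"bc_stop_date")
}
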