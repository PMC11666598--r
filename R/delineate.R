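#' Delineate menstrual cycles from daily bleeding flags
#'
#' A cycle runs from one self-reported bleeding onset to the day before the
#' next onset; day 1 is the onset day. An onset is a menstruating day with no
#' menstruating record on either of the two preceding calendar days, so a
#' single non-bleeding (or unrecorded) gap day flanked by bleeding days stays
#' inside the same menses, while two or more consecutive gap days end it.
#' Bleeding length counts the consecutive menstruating days from the onset,
#' spanning single gap days. The final, unclosed onset yields no cycle.
#' Missing menstruation flags are treated as "not reported".
#'
#' @param daily Tibble of daily records with columns `participant_id`, `date`
#'   (Date) and `menstruating` (0/1 or logical; NA = not reported).
#' @return Tibble with one row per delineated cycle: `participant_id`,
#'   `cycle_index`, `start_date`, `length` (days to the next onset) and
#'   `bleed_length`.
#' @examples
#' d <- tibble::tibble(
#'   participant_id = "P1",
#'   date = as.Date("2022-01-01") + 0:27,
#'   menstruating = c(1, 1, 1, rep(0, 24), 1)
#' )
#' delineate_cycles(d)  # one 27-day cycle, bleeding 3 days
#' @export
delineate_cycles <- function(daily) {
  required <- c("participant_id", "date", "menstruating")
  if (!all(required %in% names(daily))) {
    stop("`daily` must contain columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (nrow(daily) == 0) {
    return(tibble::tibble(participant_id = character(), cycle_index = integer(),
                          start_date = as.Date(character()),
                          length = integer(), bleed_length = integer()))
  }
  daily |>
    dplyr::arrange(.data$participant_id, .data$date) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ delineate_one(.x)) |>
    dplyr::ungroup()
}

delineate_one <- function(df) {
  empty <- tibble::tibble(cycle_index = integer(),
                          start_date = as.Date(character()),
                          length = integer(), bleed_length = integer())
  flag <- !is.na(df$menstruating) & df$menstruating > 0
  bleed_dates <- df$date[flag]
  if (length(bleed_dates) == 0) return(empty)

  is_bleed <- function(d) d %in% bleed_dates
  onsets <- bleed_dates[!is_bleed(bleed_dates - 1) & !is_bleed(bleed_dates - 2)]
  if (length(onsets) < 2) return(empty)

  n_cyc <- length(onsets) - 1
  bleed_len <- vapply(onsets[seq_len(n_cyc)], function(o) {
    end <- o
    repeat {
      if (is_bleed(end + 1)) {
        end <- end + 1
      } else if (is_bleed(end + 2)) {
        end <- end + 2  # single gap day flanked by bleeding
      } else {
        break
      }
    }
    as.integer(end - o + 1)
  }, integer(1))

  tibble::tibble(
    cycle_index = seq_len(n_cyc),
    start_date = onsets[seq_len(n_cyc)],
    length = as.integer(diff(onsets)),
    bleed_length = bleed_len
  )
}
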