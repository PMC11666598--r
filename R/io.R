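#' Write a simulated cohort to delimited text files
#'
#' Writes `daily.csv`, `participants.csv` and `truth.csv` (UTF-8,
#' comma-separated, header row, ISO-8601 dates) into a directory.
#'
#' @param sim List returned by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(daily = file.path(dir, "daily.csv"),
             participants = file.path(dir, "participants.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(sim$daily, paths["daily"])
  readr::write_csv(sim$participants, paths["participants"])
  readr::write_csv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Read daily wearable records
#'
#' @param path Path to a `daily.csv` (columns `participant_id`, `date`,
#'   `rhr_bpm`, `rmssd_ms`, `kj_prior_day`, `menstruating`).
#' @return Tibble with typed columns.
#' @export
read_daily <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date(),
    rhr_bpm = readr::col_double(),
    rmssd_ms = readr::col_double(),
    kj_prior_day = readr::col_double(),
    menstruating = readr::col_integer()
  ))
}

#' Read participant metadata
#'
#' @param path Path to a `participants.csv` (columns `participant_id`,
#'   `age_years`, `bmi`, `cohort`, `bc_start_date`, `bc_stop_date`).
#' @return Tibble with typed columns.
#' @export
read_participants <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    age_years = readr::col_double(),
    bmi = readr::col_double(),
    cohort = readr::col_character(),
    bc_start_date = readr::col_date(),
    bc_stop_date = readr::col_date()
  ))
}
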