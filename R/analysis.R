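# Analyses over a history table: recruitment-length change at follow-up,
# outcome-change detection by run-length comparison, and
# follow-up-corrected status counts.
#
# All three operate on the long-format history table (one registry entry
# version per row, versions ascending within trial) and use calendar-aware
# period arithmetic: adding one year lands on the same month and day of the
# next year, with Feb-29 falling back to Feb-28 (`lubridate::%m+%`).

#' Latest version of a trial active at a given date
#'
#' The registry entry version in force at `date` is the latest version whose
#' `version_date` is on or before `date` (boundary inclusive). When two rows
#' share a version date the later row wins.
#'
#' @param history History table.
#' @param trial One trial id.
#' @param date ISO-8601 date (or `Date`).
#' @return One-row tibble, or `NULL` when the trial is absent or its first
#'   version postdates `date`.
#' @export
version_active_at <- function(history, trial, date) {
  idc <- id_column(history_registry(history))
  rows <- history[
    !is.na(history[[idc]]) & history[[idc]] == trial &
      !is.na(history$version_date) &
      as.Date(history$version_date) <= as.Date(date),
  ]
  if (nrow(rows) == 0) return(NULL)
  rows[nrow(rows), ]
}

#' Change in recruitment period length at fixed follow-up
#'
#' For each trial the launch recruitment period runs from the study start
#' date to the primary completion date as reported on the earliest version
#' whose overall status is `"Recruiting"` and where both dates are present.
#' The follow-up period uses the same two dates from the version active at
#' `followup` after the launch start date (latest version with
#' `version_date` on or before that horizon and both dates present). Trials
#' with no qualifying launch version — no historical version posted after
#' the trial started recruiting — are excluded; trials with a launch version
#' but no qualifying follow-up version are retained with missing follow-up
#' fields. The percentage change is rendered as an integer percentage with a
#' `%` suffix: `round(100 * length_at_followup / length_at_launch - 100)`.
#'
#' @param history ClinicalTrials.gov history table.
#' @param followup Follow-up period as a [lubridate::period()] (default one
#'   year).
#' @return Tibble with one row per qualifying trial: `nctid`,
#'   `recruitment_length_at_launch` and `recruitment_length_at_fup` (days),
#'   `recruitment_length_change` (text, e.g. `"50%"`).
#' @export
recruitment_change <- function(history, followup = lubridate::years(1)) {
  stopifnot(history_registry(history) == "ctgov")
  launch_dates <- history |>
    dplyr::filter(
      .data$overall_status == "Recruiting" &
        !is.na(.data$study_start_date) &
        !is.na(.data$primary_completion_date)
    ) |>
    dplyr::group_by(.data$nctid) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select(
      "nctid",
      launch_start_date = "study_start_date",
      launch_completion_date = "primary_completion_date"
    )

  hv <- history |>
    dplyr::left_join(launch_dates, by = "nctid") |>
    dplyr::filter(!is.na(.data$launch_start_date))

  dates_fup <- hv |>
    dplyr::filter(
      as.Date(.data$version_date) <=
        (as.Date(.data$launch_start_date) %m+% followup) &
        !is.na(.data$study_start_date) &
        !is.na(.data$primary_completion_date)
    ) |>
    dplyr::group_by(.data$nctid) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select(
      "nctid",
      start_date_fup = "study_start_date",
      completion_date_fup = "primary_completion_date"
    )

  launch_dates |>
    dplyr::left_join(dates_fup, by = "nctid") |>
    dplyr::mutate(
      recruitment_length_at_launch = as.numeric(
        as.Date(.data$launch_completion_date) -
          as.Date(.data$launch_start_date)
      ),
      recruitment_length_at_fup = as.numeric(
        as.Date(.data$completion_date_fup) - as.Date(.data$start_date_fup)
      ),
      recruitment_length_change = ifelse(
        is.na(.data$recruitment_length_at_fup),
        NA_character_,
        paste0(
          round(
            100 * .data$recruitment_length_at_fup /
              .data$recruitment_length_at_launch - 100,
            digits = 0
          ),
          "%"
        )
      )
    ) |>
    dplyr::select(
      "nctid", "recruitment_length_at_launch", "recruitment_length_at_fup",
      "recruitment_length_change"
    )
}

# Outcome columns whose concatenation defines a "run" for change detection.
outcome_run_key <- function(history, registry) {
  if (registry == "drks") {
    paste(
      history$drksid, history$primary_outcomes, history$secondary_outcomes
    )
  } else {
    paste(history$nctid, history$outcome_measures)
  }
}

#' Detect changes to registered outcome measures
#'
#' Identifies runs — maximal stretches of consecutive versions of one trial
#' whose JSON-encoded outcome measures are byte-identical — and emits the
#' first row of each run. Because the JSON encoding is canonical, any
#' structural difference, down to a single whitespace character inside an
#' outcome, opens a new run; a trial's first version always opens one. For
#' DRKS histories the compared fields are `primary_outcomes` and
#' `secondary_outcomes`; for ClinicalTrials.gov, `outcome_measures`.
#' Deciding which detected changes are substantive (versus typo fixes) is
#' deliberately left to human curation of the output.
#'
#' @param history History table (rows grouped by trial, versions ascending).
#' @return Tibble with one row per run: trial id, `version_date` on which
#'   the outcomes changed (or first appeared), the outcome column(s), and
#'   `run_index`.
#' @export
outcome_change_runs <- function(history) {
  registry <- history_registry(history)
  if (nrow(history) == 0) {
    out <- history[0, ]
    out$run_index <- integer(0)
    return(out)
  }
  runs <- rle(outcome_run_key(history, registry))
  hv <- history
  hv$run_index <- rep(seq_along(runs$lengths), runs$lengths)
  keep <- if (registry == "drks") {
    c("drksid", "version_date", "primary_outcomes", "secondary_outcomes")
  } else {
    c("nctid", "version_date", "outcome_measures")
  }
  hv |>
    dplyr::group_by(.data$run_index) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c(keep, "run_index")))
}

#' Trial statuses assessed at a common follow-up horizon
#'
#' Corrects for variable follow-up time: every trial's overall status is
#' read from the registry entry version active at `followup` after its first
#' version date, and trials registered less than `followup` before `today`
#' are excluded (their horizon has not yet been reached, so counting them
#' would bias stopped-trial rates downward). A trial is `stopped` when that
#' at-horizon status is `"Suspended"`, `"Terminated"` or `"Withdrawn"`;
#' status changes after the horizon deliberately do not count.
#'
#' @param history ClinicalTrials.gov history table.
#' @param followup Follow-up period as a [lubridate::period()] (default five
#'   years).
#' @param today Reference date for the exclusion rule (default the current
#'   date; fix it for reproducible analyses).
#' @return Tibble with one row per included trial: `nctid`,
#'   `first_version_date`, `version_date` (of the at-horizon version),
#'   `overall_status`, `stopped`.
#' @export
followup_status <- function(history, followup = lubridate::years(5),
                            today = Sys.Date()) {
  stopifnot(history_registry(history) == "ctgov")
  stopped_statuses <- c("Suspended", "Terminated", "Withdrawn")
  history |>
    dplyr::group_by(.data$nctid) |>
    dplyr::mutate(first_version_date = min(.data$version_date)) |>
    dplyr::filter(
      as.Date(.data$version_date) <=
        (as.Date(.data$first_version_date) %m+% followup)
    ) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::filter(
      as.Date(.data$first_version_date) <= (as.Date(today) %m-% followup)
    ) |>
    dplyr::select(
      "nctid", "first_version_date", "version_date", "overall_status"
    ) |>
    dplyr::mutate(
      stopped = .data$overall_status %in% stopped_statuses
    )
}

# Round half away from zero at `digits` decimals (base round() rounds half
# to even, which would turn 14.45 into 14.4).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Latest version of every trial in a history table
#'
#' The naive view of a cohort: one row per trial, its most recent registry
#' entry version. Counting stopped trials here ignores variable follow-up
#' time; compare [followup_status()].
#'
#' @param history History table.
#' @return Tibble with the last row of each trial.
#' @export
latest_versions <- function(history) {
  idc <- id_column(history_registry(history))
  history |>
    dplyr::group_by(.data[[idc]]) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
}

#' Stopped trials as a fraction of an assessed cohort
#'
#' Counts the `stopped` flags of a [followup_status()] result and reports
#' the percentage to one decimal, rounding half up (so 10 of 69 reports
#' 14.5).
#'
#' @param statuses Tibble with a logical `stopped` column (e.g. from
#'   [followup_status()]).
#' @return List with `n_stopped`, `n_total` and `percent`.
#' @export
#' @examples
#' statuses <- tibble::tibble(stopped = rep(c(TRUE, FALSE), c(16, 77)))
#' stopped_fraction(statuses)
stopped_fraction <- function(statuses) {
  if (is.null(statuses) || nrow(statuses) == 0) {
    stop("stopped_fraction() is undefined for an empty cohort", call. = FALSE)
  }
  n_stopped <- sum(statuses$stopped)
  n_total <- nrow(statuses)
  list(
    n_stopped = n_stopped,
    n_total = n_total,
    percent = round_half_up(100 * n_stopped / n_total, 1)
  )
}
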