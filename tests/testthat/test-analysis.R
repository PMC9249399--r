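# Minimal ctgov history builder for analysis tests: one trial, one row per
# version, only the columns the analyses read.
ctgov_history <- function(nctid, version_dates, statuses,
                          starts = NA, pcds = NA, outcomes = NA) {
  n <- length(version_dates)
  dplyr::bind_rows(lapply(seq_len(n), function(v) {
    ctgov_row(
      nctid = nctid, version_number = as.integer(v),
      version_date = version_dates[v],
      overall_status = rep_len(statuses, n)[v],
      study_start_date = rep_len(starts, n)[v],
      primary_completion_date = rep_len(pcds, n)[v],
      outcome_measures = rep_len(outcomes, n)[v]
    )
  }))
}

test_that("version_active_at picks the latest version on or before a date", {
  hv <- ctgov_history(
    "NCT00000001", c("2020-01-01", "2020-06-01", "2021-01-01"), "Recruiting"
  )
  expect_identical(
    version_active_at(hv, "NCT00000001", "2020-06-01")$version_number, 2L
  )
  expect_null(version_active_at(hv, "NCT00000001", "2019-12-31"))
  expect_null(version_active_at(hv, "NCT09999999", "2021-01-01"))
  # monotone: a later query date never returns an earlier version
  v1 <- version_active_at(hv, "NCT00000001", "2020-07-01")$version_number
  v2 <- version_active_at(hv, "NCT00000001", "2021-07-01")$version_number
  expect_gte(v2, v1)

  # same-date tie: the later row wins
  tie <- ctgov_history(
    "NCT00000002", c("2020-01-01", "2020-01-01"), c("Recruiting", "Suspended")
  )
  expect_identical(
    version_active_at(tie, "NCT00000002", "2020-01-01")$overall_status,
    "Suspended"
  )
})

test_that("recruitment length change follows the launch/follow-up contrast", {
  # launch: 200 days (2020-01-01 .. 2020-07-19); at follow-up the completion
  # date moved out to 300 days
  hv <- ctgov_history(
    "NCT00000001",
    c("2020-01-01", "2020-06-01"),
    "Recruiting",
    starts = "2020-01-01",
    pcds = c("2020-07-19", "2020-10-27")
  )
  out <- recruitment_change(hv, lubridate::years(1))
  expect_equal(out$recruitment_length_at_launch, 200)
  expect_equal(out$recruitment_length_at_fup, 300)
  expect_identical(out$recruitment_length_change, "50%")

  # unchanged dates: identity
  same <- ctgov_history(
    "NCT00000002", c("2020-01-01", "2020-03-01"), "Recruiting",
    starts = "2020-01-01", pcds = "2020-07-19"
  )
  expect_identical(recruitment_change(same)$recruitment_length_change, "0%")

  # a trial never posted as Recruiting is excluded entirely
  never <- ctgov_history(
    "NCT00000003", c("2020-01-01", "2020-03-01"), "Active not recruiting",
    starts = "2020-01-01", pcds = "2020-07-19"
  )
  expect_equal(nrow(recruitment_change(never)), 0)

  # versions after the follow-up horizon do not contribute follow-up dates
  late <- ctgov_history(
    "NCT00000004",
    c("2020-01-01", "2021-06-01"),
    "Recruiting",
    starts = "2020-01-01",
    pcds = c("2020-07-19", "2022-07-19")
  )
  expect_identical(
    recruitment_change(late, lubridate::years(1))$recruitment_length_change,
    "0%"
  )
})

test_that("outcome runs split exactly at byte-level encoding changes", {
  enc <- function(x) encode_nested(x)
  hv <- ctgov_history(
    "NCT00000001",
    c("2020-01-01", "2020-02-01", "2020-03-01", "2020-04-01"),
    "Recruiting",
    outcomes = c(enc("A"), enc("A"), enc("B"), enc("A"))
  )
  out <- outcome_change_runs(hv)
  expect_equal(nrow(out), 3)
  expect_identical(out$version_date, c("2020-01-01", "2020-03-01", "2020-04-01"))
  expect_identical(out$run_index, 1:3)

  all_same <- ctgov_history(
    "NCT00000002", c("2020-01-01", "2020-02-01"), "Recruiting",
    outcomes = enc("stable outcome")
  )
  expect_equal(nrow(outcome_change_runs(all_same)), 1)

  # one internal space is a change
  ws <- ctgov_history(
    "NCT00000003", c("2020-01-01", "2020-02-01"), "Recruiting",
    outcomes = c(enc("OS at 12 months"), enc("OS at  12 months"))
  )
  expect_equal(nrow(outcome_change_runs(ws)), 2)
})

test_that("detected runs equal the brute-force adjacent comparison", {
  truth <- simulate_histories(sim_config(
    n_trials = 20, registry = "drks", seed = 55,
    p_outcome_edit = 0.3, p_whitespace_edit = 0.2
  ))
  hv <- truth$records
  out <- outcome_change_runs(hv)

  # independent oracle: linear scan comparing adjacent rows per trial
  expected <- 0L
  for (id in unique(hv$drksid)) {
    rows <- hv[hv$drksid == id, ]
    expected <- expected + 1L
    if (nrow(rows) > 1) {
      for (i in 2:nrow(rows)) {
        if (!identical(rows$primary_outcomes[i], rows$primary_outcomes[i - 1]) ||
          !identical(rows$secondary_outcomes[i], rows$secondary_outcomes[i - 1])) {
          expected <- expected + 1L
        }
      }
    }
  }
  expect_equal(nrow(out), expected)
})

test_that("follow-up correction classifies at the horizon, not at latest", {
  today <- as.Date("2022-01-05")
  hv <- dplyr::bind_rows(
    # registered 6y ago, terminated at +4y: included, stopped at horizon
    ctgov_history(
      "NCT00000001", c("2016-01-05", "2020-01-05"),
      c("Recruiting", "Terminated")
    ),
    # registered 1y ago: requisite follow-up not yet passed, excluded
    ctgov_history("NCT00000002", "2021-01-05", "Recruiting"),
    # stopped only after the 5-year mark: included but not stopped
    ctgov_history(
      "NCT00000003", c("2015-01-05", "2021-06-01"),
      c("Recruiting", "Withdrawn")
    )
  )
  out <- followup_status(hv, lubridate::years(5), today = today)
  expect_setequal(out$nctid, c("NCT00000001", "NCT00000003"))
  expect_identical(out$stopped[out$nctid == "NCT00000001"], TRUE)
  expect_identical(out$stopped[out$nctid == "NCT00000003"], FALSE)
})

test_that("lengthening follow-up never adds trials to the included set", {
  truth <- simulate_histories(
    sim_config(n_trials = 40, registry = "ctgov", seed = 56)
  )
  today <- max(as.Date(truth$records$version_date))
  included <- function(years) {
    followup_status(truth$records, lubridate::years(years), today)$nctid
  }
  sets <- lapply(c(1, 3, 5, 7), included)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("status-at-horizon recovery is exact on a simulated cohort", {
  truth <- simulate_histories(sim_config(
    n_trials = 200, registry = "ctgov", seed = 57,
    version_count_range = c(2L, 6L)
  ))
  hv <- truth$records
  today <- max(as.Date(hv$version_date))
  followup <- lubridate::years(2)
  out <- followup_status(hv, followup, today = today)

  # independent oracle in base R over the known simulated transition times
  expected_ids <- character(0)
  expected_stopped <- character(0)
  for (id in unique(hv$nctid)) {
    rows <- hv[hv$nctid == id, ]
    first <- min(as.Date(rows$version_date))
    if (first > lubridate::add_with_rollback(today, -followup)) next
    horizon <- lubridate::add_with_rollback(first, followup)
    at <- rows[as.Date(rows$version_date) <= horizon, ]
    status <- at$overall_status[nrow(at)]
    expected_ids <- c(expected_ids, id)
    if (status %in% STOPPED) expected_stopped <- c(expected_stopped, id)
  }
  expect_setequal(out$nctid, expected_ids)
  expect_setequal(out$nctid[out$stopped], expected_stopped)

  # the bias mechanism: naive latest-status counting finds at least as many
  # stopped trials as the horizon-corrected count
  expect_gte(
    sum(naive_stopped(hv)$stopped), sum(out$stopped)
  )
})

test_that("stopped fractions report one decimal, rounding half up", {
  frac <- function(k, n) {
    stopped_fraction(tibble::tibble(stopped = rep(c(TRUE, FALSE), c(k, n - k))))
  }
  expect_equal(frac(16, 93)$percent, 17.2)
  expect_equal(frac(0, 10)$percent, 0)
  # 10/69 = 14.4927...: round-half-up reports 14.5
  expect_equal(frac(10, 69)$percent, 14.5)
  expect_error(
    stopped_fraction(tibble::tibble(stopped = logical(0))), "empty"
  )
})
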