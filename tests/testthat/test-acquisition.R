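test_that("fetch_page returns transport output or the failure marker", {
  ok <- function(url) "<html>page</html>"
  expect_identical(
    fetch_page("http://x.test/a", fast_policy(), ok), "<html>page</html>"
  )

  calls <- 0L
  failing <- function(url) {
    calls <<- calls + 1L
    NULL
  }
  out <- fetch_page("http://x.test/a", fast_policy(retries = 3L), failing)
  expect_null(out)
  expect_identical(calls, 3L)

  # transport exceptions are swallowed into the marker, never raised
  throwing <- function(url) stop("boom")
  expect_null(fetch_page("http://x.test/a", fast_policy(), throwing))
})

test_that("consecutive fetches to one host honour the minimum delay", {
  clock <- new.env()
  clock$t <- 0
  clock$sleeps <- numeric(0)
  policy <- fetch_policy(
    min_delay_seconds = 5,
    now_fun = function() clock$t,
    sleep_fun = function(s) {
      clock$sleeps <- c(clock$sleeps, s)
      clock$t <- clock$t + s
    }
  )
  transport <- function(url) {
    clock$t <- clock$t + 0.1 # request latency
    "<html/>"
  }
  fetch_page("http://polite.test/1", policy, transport)
  fetch_page("http://polite.test/2", policy, transport)
  expect_length(clock$sleeps, 1)
  expect_gte(clock$sleeps[1], 5 - 0.2)
})

test_that("download assembles one row per version across a cohort", {
  truth <- simulate_histories(
    sim_config(n_trials = 2, registry = "ctgov", seed = 14)
  )
  ids <- truth_ids(truth)
  per_trial <- table(truth$records$nctid)

  hv <- quiet_download(
    ids, policy = fast_policy(), transport = fixture_transport(truth)
  )
  expect_equal(nrow(hv), sum(per_trial))
  expect_equal(as.data.frame(hv), as.data.frame(truth$records))

  f <- withr::local_tempfile(fileext = ".csv")
  out <- quiet_download(
    ids, f, policy = fast_policy(), transport = fixture_transport(truth)
  )
  expect_true(out$complete)
  expect_identical(out$error_rows, 0L)
  expect_equal(out$rows_written, sum(per_trial))
  expect_equal(as.data.frame(read_history_csv(f)), as.data.frame(truth$records))
})

test_that("a failing version page becomes an Error row, not a crash", {
  truth <- simulate_histories(
    sim_config(n_trials = 2, registry = "ctgov", seed = 15)
  )
  ids <- truth_ids(truth)
  bad_key <- paste0(ids[1], "_2")
  base <- fixture_transport(truth)
  transport <- function(url) {
    if (grepl(paste0(ids[1], "\\?V_2$"), url)) NULL else base(url)
  }
  f <- withr::local_tempfile(fileext = ".csv")
  out <- quiet_download(ids, f, policy = fast_policy(), transport = transport)
  expect_false(out$complete)
  expect_identical(out$error_rows, 1L)
  hv <- read_history_csv(f)
  bad_row <- hv[hv$nctid == ids[1] & hv$version_number == 2L, ]
  expect_identical(bad_row$overall_status, "Error")
})

test_that("an empty cohort downloads zero rows, complete", {
  f <- withr::local_tempfile(fileext = ".csv")
  out <- quiet_download(
    character(0), f, policy = fast_policy(),
    transport = function(url) stop("no requests expected")
  )
  expect_true(out$complete)
  expect_identical(out$rows_written, 0L)
})

test_that("an unwritable output path fails before any fetch", {
  calls <- 0L
  transport <- function(url) {
    calls <<- calls + 1L
    "<html/>"
  }
  expect_error(
    quiet_download(
      "NCT00000001", file.path(tempdir(), "no-such-dir", "x.csv"),
      policy = fast_policy(), transport = transport
    ),
    "cannot write"
  )
  expect_identical(calls, 0L)
})

test_that("a failed date index yields a whole-trial placeholder row", {
  truth <- simulate_histories(
    sim_config(n_trials = 2, registry = "ctgov", seed = 16)
  )
  ids <- truth_ids(truth)
  base <- fixture_transport(truth)
  no_index <- function(url) {
    if (grepl(paste0(ids[1], "$"), url)) NULL else base(url)
  }
  f <- withr::local_tempfile(fileext = ".csv")
  out <- quiet_download(ids, f, policy = fast_policy(), transport = no_index)
  expect_false(out$complete)
  hv <- read_history_csv(f)
  placeholder <- hv[hv$overall_status == "Error" & !is.na(hv$overall_status), ]
  expect_equal(nrow(placeholder), 1)
  expect_true(is.na(placeholder$version_number))

  # resume re-fetches the whole trial from its index
  out2 <- quiet_resume(f, policy = fast_policy(), transport = base)
  expect_true(out2$complete)
  expect_equal(
    as.data.frame(read_history_csv(f)), as.data.frame(truth$records)
  )
})

test_that("resume repairs exactly the Error rows and is idempotent", {
  truth <- simulate_histories(
    sim_config(n_trials = 3, registry = "drks", seed = 17)
  )
  ids <- truth_ids(truth)
  bad_key <- paste0(ids[2], "/version/1$")
  base <- fixture_transport(truth)
  flaky <- function(url) if (grepl(bad_key, url)) NULL else base(url)

  f <- withr::local_tempfile(fileext = ".csv")
  out <- quiet_download(ids, f, policy = fast_policy(), transport = flaky)
  expect_false(out$complete)

  # transport still failing: the Error row persists
  out_still <- quiet_resume(f, policy = fast_policy(), transport = flaky)
  expect_false(out_still$complete)
  expect_identical(out_still$error_rows, 1L)

  # repaired transport: converges to the fully-successful download
  out_fixed <- quiet_resume(f, policy = fast_policy(), transport = base)
  expect_true(out_fixed$complete)
  expect_equal(as.data.frame(read_history_csv(f)), as.data.frame(truth$records))

  # no Error rows: file untouched byte-for-byte, no fetches made
  bytes_before <- readBin(f, "raw", file.size(f))
  fetches <- 0L
  counting <- function(url) {
    fetches <<- fetches + 1L
    base(url)
  }
  out_idem <- quiet_resume(f, policy = fast_policy(), transport = counting)
  expect_true(out_idem$complete)
  expect_identical(fetches, 0L)
  expect_identical(readBin(f, "raw", file.size(f)), bytes_before)
})

test_that("iterated resume converges under an eventually-good transport", {
  truth <- simulate_histories(
    sim_config(n_trials = 4, registry = "ctgov", seed = 18)
  )
  ids <- truth_ids(truth)
  base <- fixture_transport(truth)
  # each version URL fails on its first two requests, then succeeds
  seen <- new.env()
  flaky <- function(url) {
    n <- (seen[[url]] <- (if (is.null(seen[[url]])) 0L else seen[[url]]) + 1L)
    if (grepl("V_", url) && n <= 2) NULL else base(url)
  }
  f <- withr::local_tempfile(fileext = ".csv")
  out <- quiet_download(ids, f, policy = fast_policy(), transport = flaky)
  for (i in 1:5) {
    if (out$complete) break
    out <- quiet_resume(f, policy = fast_policy(), transport = flaky)
  }
  expect_true(out$complete)

  reference <- withr::local_tempfile(fileext = ".csv")
  quiet_download(ids, reference, policy = fast_policy(), transport = base)
  expect_identical(
    readr::read_file(f), readr::read_file(reference)
  )
})

test_that("cohort files parse per registry dialect and de-duplicate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "NCT Number,Title",
    "NCT00000001,A", "NCT00000002,B", "NCT00000001,A again", "NCT00000003,C"
  ), f)
  expect_identical(
    read_cohort(f, "ctgov"), c("NCT00000001", "NCT00000002", "NCT00000003")
  )

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "drksId;title", "DRKS00000011;x", "DRKS00000012;y"
  ), g)
  expect_identical(read_cohort(g, "drks"), c("DRKS00000011", "DRKS00000012"))

  expect_error(read_cohort(g, "ctgov"), "NCT Number")
})
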