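# Acquisition: polite fetching of all versions for a cohort of trials,
# assembly of the long-format history table, and the Error-sentinel resume
# protocol.
#
# The transport is injected as a plain function(url) -> html text, or NULL on
# failure. This keeps the whole download loop testable offline against
# rendered fixture pages; the live HTTP transport is a thin, best-effort
# wrapper (registry sites redesign their HTML at will, and the parsers
# target the classic dialects).

# Per-host timestamps of the last request, for inter-request delays.
.last_request <- new.env(parent = emptyenv())

#' Fetch policy for polite scraping
#'
#' @param min_delay_seconds Minimum spacing between consecutive requests to
#'   the same host, in seconds. Registry servers are shared infrastructure;
#'   the conservative default is 5 s and is configurable, not hard-coded.
#' @param user_agent User-agent string identifying the scraper.
#' @param max_retries_per_page Total attempts per page before giving up and
#'   returning the failure marker.
#' @param respect_robots Honour robots directives in the live transport.
#' @param now_fun,sleep_fun Clock and sleep functions; injectable so that
#'   delay behaviour is testable without waiting.
#' @return A `fetch_policy` list.
#' @export
fetch_policy <- function(min_delay_seconds = 5,
                         user_agent = "registryhist R package",
                         max_retries_per_page = 3L,
                         respect_robots = TRUE,
                         now_fun = function() as.numeric(Sys.time()),
                         sleep_fun = Sys.sleep) {
  stopifnot(
    min_delay_seconds >= 0,
    max_retries_per_page >= 0,
    is.character(user_agent), length(user_agent) == 1
  )
  structure(
    list(
      min_delay_seconds = min_delay_seconds,
      user_agent = user_agent,
      max_retries_per_page = as.integer(max_retries_per_page),
      respect_robots = isTRUE(respect_robots),
      now_fun = now_fun,
      sleep_fun = sleep_fun
    ),
    class = "fetch_policy"
  )
}

url_host <- function(url) {
  sub("^[a-z]+://([^/]+).*$", "\\1", url)
}

# Block until the per-host delay has elapsed, then stamp the request time.
wait_politely <- function(url, policy) {
  if (policy$min_delay_seconds <= 0) return(invisible())
  host <- url_host(url)
  now <- policy$now_fun()
  last <- .last_request[[host]]
  if (!is.null(last)) {
    remaining <- policy$min_delay_seconds - (now - last)
    if (remaining > 0) policy$sleep_fun(remaining)
  }
  .last_request[[host]] <- policy$now_fun()
  invisible()
}

#' Fetch one page through a transport, politely and without raising
#'
#' Enforces the policy's inter-request delay, attempts the transport up to
#' `max_retries_per_page` times, and returns the page text on success or
#' `NULL` (the failure marker) when all attempts fail. Network failure never
#' raises; it surfaces only as the marker, which the download loop records as
#' an `"Error"` sentinel row.
#'
#' @param url Page URL (fixture transports interpret the trial id and version
#'   embedded in it).
#' @param policy A [fetch_policy()].
#' @param transport `function(url) -> html text or NULL`.
#' @return Character HTML, or `NULL` on failure.
#' @export
fetch_page <- function(url, policy = fetch_policy(), transport) {
  attempts <- max(1L, policy$max_retries_per_page)
  for (i in seq_len(attempts)) {
    wait_politely(url, policy)
    html <- tryCatch(transport(url), error = function(e) NULL)
    if (is.character(html) && length(html) == 1 && !is.na(html)) {
      return(html)
    }
  }
  NULL
}

# URL builders for the two registries. Fixture transports parse the trial id
# and version back out of these, so live and offline modes share one loop.
index_url <- function(registry, id) {
  if (registry == "ctgov") {
    paste0("https://classic.clinicaltrials.gov/ct2/history/", id)
  } else {
    paste0("https://drks.de/search/en/trial/", id, "/versions")
  }
}

version_url <- function(registry, id, version_number) {
  if (registry == "ctgov") {
    paste0(
      "https://classic.clinicaltrials.gov/ct2/history/", id,
      "?V_", version_number
    )
  } else {
    paste0(
      "https://drks.de/search/en/trial/", id, "/version/", version_number
    )
  }
}

# Decompose a URL built above into (id, version or NA).
parse_page_url <- function(url) {
  id <- stringr::str_match(url, "(NCT[0-9]{8}|DRKS[0-9]{8})")[, 2]
  version <- stringr::str_match(url, "(?:\\?V_|/version/)([0-9]+)$")[, 2]
  list(id = id, version = as.integer(version))
}

#' Transport serving rendered fixture pages from memory
#'
#' @param truth A ground-truth object from [simulate_histories()] (or any
#'   list with `index_pages` and `pages` mappings).
#' @return A transport function for [download_history()].
#' @export
fixture_transport <- function(truth) {
  function(url) {
    loc <- parse_page_url(url)
    if (is.na(loc$id)) return(NULL)
    if (is.na(loc$version)) {
      page <- truth$index_pages[[loc$id]]
    } else {
      page <- truth$pages[[paste0(loc$id, "_", loc$version)]]
    }
    if (is.null(page)) NULL else page
  }
}

#' Transport serving fixture pages from a directory
#'
#' Reads `<id>_index.html` and `<id>_<version>.html` files as written by
#' [write_fixture_dir()].
#'
#' @param dir Directory of fixture HTML files.
#' @return A transport function for [download_history()].
#' @export
dir_transport <- function(dir) {
  function(url) {
    loc <- parse_page_url(url)
    if (is.na(loc$id)) return(NULL)
    file <- if (is.na(loc$version)) {
      file.path(dir, paste0(loc$id, "_index.html"))
    } else {
      file.path(dir, paste0(loc$id, "_", loc$version, ".html"))
    }
    if (!file.exists(file)) return(NULL)
    paste(readr::read_lines(file), collapse = "\n")
  }
}

#' Live HTTP transport (best effort)
#'
#' Fetches pages over HTTP with the policy's user agent. Registry websites
#' change their markup at any time; the parsers target the classic dialects,
#' so live use is best-effort and all tests run offline against fixtures.
#'
#' @param policy A [fetch_policy()]; supplies the user-agent header.
#' @return A transport function for [download_history()].
#' @export
http_transport <- function(policy = fetch_policy()) {
  function(url) {
    if (!requireNamespace("httr", quietly = TRUE)) {
      stop("the live transport requires the httr package", call. = FALSE)
    }
    resp <- httr::GET(url, httr::user_agent(policy$user_agent))
    if (httr::http_error(resp)) return(NULL)
    httr::content(resp, as = "text", encoding = "UTF-8")
  }
}

# Fetch + parse the version-date index for one trial; NULL on any failure.
fetch_version_dates <- function(registry, id, policy, transport) {
  html <- fetch_page(index_url(registry, id), policy, transport)
  if (is.null(html)) return(NULL)
  tryCatch(
    if (registry == "ctgov") parse_ctgov_dates(html) else parse_drks_dates(html),
    error = function(e) NULL
  )
}

# Fetch + parse one version page; always returns a one-row record (the
# sentinel row on failure).
fetch_version_record <- function(registry, id, version_number, version_date,
                                 policy, transport) {
  html <- fetch_page(
    version_url(registry, id, version_number), policy, transport
  )
  if (registry == "ctgov") {
    if (is.null(html)) {
      ctgov_error_record(id, version_number, version_date)
    } else {
      parse_ctgov_version(html, id, version_number, version_date)
    }
  } else {
    if (is.null(html)) {
      drks_error_record(id, version_number, version_date)
    } else {
      parse_drks_version(html, id, version_number, version_date)
    }
  }
}

# Placeholder row when the date index itself could not be fetched: a
# whole-trial Error row with unknown version identity, so resume re-fetches
# the trial from its index.
index_error_record <- function(registry, id) {
  if (registry == "ctgov") {
    ctgov_error_record(id, NA_integer_, NA_character_)
  } else {
    drks_error_record(id, NA_integer_, NA_character_)
  }
}

download_outcome <- function(history, registry) {
  errors <- sum(is_error_row(history, registry))
  list(
    complete = errors == 0,
    rows_written = nrow(history),
    error_rows = errors
  )
}

#' Download the complete version history for a cohort of trials
#'
#' For each trial id: fetch the history index, then each version page, one
#' history row per registry entry version. Download or parse failures never
#' abort the loop — the affected row carries the `"Error"` status sentinel
#' (a whole-trial placeholder row when the index itself failed) and the
#' outcome reports `complete = FALSE`, prompting a [resume_download()] pass.
#'
#' @param trials Character vector of trial ids, all from one registry
#'   (`NCT[0-9]{8}` or `DRKS[0-9]{8}`).
#' @param out_path Optional CSV path. When given, rows are appended to the
#'   file as they are fetched (so an interrupted run leaves a resumable
#'   file) and a download outcome is returned; when `NULL`, the assembled
#'   history table itself is returned.
#' @param policy A [fetch_policy()].
#' @param transport Page source, `function(url) -> html or NULL`; see
#'   [fixture_transport()], [dir_transport()], [http_transport()].
#' @return With `out_path`: list with `complete` (no error rows),
#'   `rows_written` and `error_rows`. Without: the history tibble.
#' @export
download_history <- function(trials, out_path = NULL,
                             policy = fetch_policy(),
                             transport = http_transport(policy)) {
  if (length(trials) == 0) {
    registry <- "ctgov"
  } else {
    registry <- infer_registry(trials)
  }
  writing <- !is.null(out_path)
  if (writing) {
    ok <- tryCatch(
      {
        readr::write_csv(empty_history(registry), out_path, na = "")
        TRUE
      },
      error = function(e) e
    )
    if (!isTRUE(ok)) {
      stop("cannot write to ", out_path, ": ", conditionMessage(ok),
        call. = FALSE
      )
    }
  }
  rows <- list()
  emit <- function(record) {
    rows[[length(rows) + 1]] <<- record
    if (writing) {
      readr::write_csv(record, out_path, na = "", append = TRUE)
    }
  }
  for (id in trials) {
    message("downloading history for ", id)
    dates <- fetch_version_dates(registry, id, policy, transport)
    if (is.null(dates)) {
      emit(index_error_record(registry, id))
      next
    }
    for (v in seq_along(dates)) {
      emit(fetch_version_record(registry, id, v, dates[v], policy, transport))
    }
  }
  history <- if (length(rows) == 0) {
    empty_history(registry)
  } else {
    dplyr::bind_rows(rows)
  }
  if (writing) download_outcome(history, registry) else history
}

#' Re-download the rows of a history CSV marked with the Error sentinel
#'
#' Reads an existing history CSV, removes rows whose status is `"Error"`,
#' fetches exactly those versions again (whole trials when the failed row was
#' an index placeholder with unknown version), and rewrites the file with
#' rows grouped by trial in their original order and sorted by version
#' number. Non-error rows are not refetched; a file with no error rows is
#' left byte-for-byte untouched. Iterating this against an
#' eventually-succeeding transport converges to `complete = TRUE`.
#'
#' @param out_path Path to a history CSV written by [download_history()].
#' @inheritParams download_history
#' @return Download outcome list (`complete`, `rows_written`, `error_rows`).
#' @export
resume_download <- function(out_path, policy = fetch_policy(),
                            transport = http_transport(policy)) {
  history <- read_history_csv(out_path)
  registry <- history_registry(history)
  idc <- id_column(registry)
  err <- is_error_row(history, registry)
  if (!any(err)) {
    return(download_outcome(history, registry))
  }
  kept <- history[!err, ]
  refetched <- list()
  for (i in which(err)) {
    id <- history[[idc]][i]
    v <- history$version_number[i]
    if (is.na(v)) {
      # index placeholder: re-fetch the whole trial
      dates <- fetch_version_dates(registry, id, policy, transport)
      if (is.null(dates)) {
        refetched[[length(refetched) + 1]] <- index_error_record(registry, id)
      } else {
        for (w in seq_along(dates)) {
          refetched[[length(refetched) + 1]] <- fetch_version_record(
            registry, id, w, dates[w], policy, transport
          )
        }
      }
    } else {
      refetched[[length(refetched) + 1]] <- fetch_version_record(
        registry, id, v, history$version_date[i], policy, transport
      )
    }
  }
  merged <- dplyr::bind_rows(c(list(kept), refetched))
  # restore grouping: trials in first-appearance order, versions ascending
  trial_order <- unique(history[[idc]])
  merged <- merged[order(
    match(merged[[idc]], trial_order), merged$version_number
  ), ]
  write_history_csv(merged, out_path)
  download_outcome(merged, registry)
}

#' Read a cohort definition file into trial ids
#'
#' ClinicalTrials.gov search exports are comma-delimited with an `NCT Number`
#' column; DRKS.de exports are semicolon-delimited with a `drksId` column.
#' Ids are returned in file order, de-duplicated keeping the first
#' occurrence.
#'
#' @param path Cohort CSV path.
#' @param registry `"ctgov"` or `"drks"`.
#' @return Character vector of trial ids.
#' @export
read_cohort <- function(path, registry = c("ctgov", "drks")) {
  registry <- match.arg(registry)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (registry == "ctgov") {
    column <- "NCT Number"
    cohort <- readr::read_csv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  } else {
    column <- "drksId"
    cohort <- readr::read_delim(
      path,
      delim = ";",
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  if (!column %in% names(cohort)) {
    stop("cohort file lacks column `", column, "`: ", path, call. = FALSE)
  }
  unique(cohort[[column]])
}
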