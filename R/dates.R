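# Date normalization for the two registry dialects.
#
# ClinicalTrials.gov prints English "Month Day, Year" or month-only
# "Month Year"; month-only dates are rounded to day 01 and flagged with
# precision "month". DRKS prints slash-delimited YYYY/MM/DD, always
# day-precise.

#' Normalize a ClinicalTrials.gov date string to ISO-8601
#'
#' Accepts `"Month Day, Year"` (e.g. `"September 9, 2009"`) or month-only
#' `"Month Year"` (e.g. `"September 2009"`). Month-only dates are rounded to
#' the first of the month and marked with precision `"month"`; full dates are
#' marked `"day"`.
#'
#' @param text A single date string in the registry's English format.
#' @return List with elements `date` (ISO-8601 string) and `precision`
#'   (`"day"` or `"month"`).
#' @export
#' @examples
#' normalize_ctgov_date("September 2009")
#' normalize_ctgov_date("September 9, 2009")
normalize_ctgov_date <- function(text) {
  if (length(text) != 1 || is.na(text)) {
    stop("normalize_ctgov_date() expects one date string", call. = FALSE)
  }
  text <- trimws(text)
  m_day <- stringr::str_match(
    text, "^([A-Za-z]+) ([0-9]{1,2}), ([0-9]{4})$"
  )
  m_month <- stringr::str_match(text, "^([A-Za-z]+) ([0-9]{4})$")
  if (!is.na(m_day[1, 1])) {
    month <- month_number(m_day[1, 2], text)
    day <- as.integer(m_day[1, 3])
    year <- as.integer(m_day[1, 4])
    precision <- "day"
  } else if (!is.na(m_month[1, 1])) {
    month <- month_number(m_month[1, 2], text)
    day <- 1L
    year <- as.integer(m_month[1, 3])
    precision <- "month"
  } else {
    stop("unrecognized registry date: \"", text, "\"", call. = FALSE)
  }
  iso <- sprintf("%04d-%02d-%02d", year, month, day)
  if (is.na(as.Date(iso, format = "%Y-%m-%d"))) {
    stop("invalid calendar date: \"", text, "\"", call. = FALSE)
  }
  list(date = iso, precision = precision)
}

# English month name -> month number; error preserves original text.
month_number <- function(name, original) {
  idx <- match(tolower(name), tolower(month.name))
  if (is.na(idx)) {
    stop("unrecognized month in registry date: \"", original, "\"",
      call. = FALSE
    )
  }
  idx
}

#' Normalize a DRKS.de date string to ISO-8601
#'
#' DRKS version pages print dates as `YYYY/MM/DD`; they are normalized to
#' hyphenated ISO-8601 and are always day-precise.
#'
#' @param text A single `YYYY/MM/DD` string.
#' @return ISO-8601 date string.
#' @export
#' @examples
#' normalize_drks_date("2019/03/01")
normalize_drks_date <- function(text) {
  if (length(text) != 1 || is.na(text)) {
    stop("normalize_drks_date() expects one date string", call. = FALSE)
  }
  text <- trimws(text)
  if (!grepl("^[0-9]{4}/[0-9]{2}/[0-9]{2}$", text)) {
    stop("unrecognized DRKS date: \"", text, "\"", call. = FALSE)
  }
  iso <- gsub("/", "-", text, fixed = TRUE)
  if (is.na(as.Date(iso, format = "%Y-%m-%d"))) {
    stop("invalid calendar date: \"", text, "\"", call. = FALSE)
  }
  iso
}

# Render an ISO date back into the ClinicalTrials.gov display dialect.
# precision "month" -> "September 2009"; "day" -> "September 9, 2009".
format_ctgov_date <- function(iso, precision = "day") {
  d <- as.Date(iso)
  month <- month.name[as.integer(format(d, "%m"))]
  if (precision == "month") {
    paste(month, format(d, "%Y"))
  } else {
    paste0(month, " ", as.integer(format(d, "%d")), ", ", format(d, "%Y"))
  }
}

# Render an ISO date in the DRKS slash dialect.
format_drks_date <- function(iso) {
  gsub("-", "/", iso, fixed = TRUE)
}
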