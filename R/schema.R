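#' registryhist: clinical trial registry version histories
#'
#' Download, parse and analyse complete version histories of clinical trial
#' registry entries from ClinicalTrials.gov (classic history pages) and
#' DRKS.de (change-history pages). Histories are returned as long-format
#' tables with one registry entry version per row; nested registry structures
#' (eligibility criteria, outcome measures, contacts, sponsors) are stored as
#' canonical JSON strings so that byte equality of two cells is equivalent to
#' structural equality of their contents.
#'
#' @importFrom rlang .data
#' @importFrom lubridate %m+% %m-%
#' @keywords internal
"_PACKAGE"

# Reserved status value marking a failed download/parse; the resume protocol
# keys on this, so it must never collide with a legitimate registry status.
ERROR_SENTINEL <- "Error"

#' Column order of the long-format history table
#'
#' One registry entry version per row. The first three columns identify the
#' version (trial id, 1-based version number, ISO-8601 version date); the
#' remainder are the extracted data points: 16 for ClinicalTrials.gov and 13
#' for DRKS.de (a date and its precision count as two data points).
#'
#' @param registry `"ctgov"` or `"drks"`.
#' @return Character vector of column names in serialization order.
#' @export
#' @examples
#' history_columns("ctgov")
history_columns <- function(registry = c("ctgov", "drks")) {
  registry <- match.arg(registry)
  if (registry == "ctgov") {
    c(
      "nctid", "version_number", "version_date",
      "overall_status", "enrolment",
      "study_start_date", "start_date_precision",
      "primary_completion_date", "primary_completion_date_precision",
      "primary_completion_date_type",
      "min_age", "max_age", "sex", "gender_based",
      "accepts_healthy_volunteers",
      "criteria", "outcome_measures", "contacts", "sponsors"
    )
  } else {
    c(
      "drksid", "version_number", "version_date",
      "recruitment_status", "start_date", "closing_date",
      "enrolment", "enrolment_type",
      "min_age", "max_age", "gender",
      "inclusion_criteria_additional", "exclusion_criteria",
      "primary_outcomes", "secondary_outcomes", "contacts"
    )
  }
}

# Columns holding something other than plain text.
history_col_types <- function(registry) {
  if (registry == "ctgov") {
    list(integer = "version_number")
  } else {
    list(integer = c("version_number", "enrolment"))
  }
}

#' Identify which registry a history table belongs to
#'
#' @param history A history table as returned by [download_history()] or
#'   [read_history_csv()].
#' @return `"ctgov"` or `"drks"`.
#' @export
history_registry <- function(history) {
  if ("nctid" %in% names(history)) return("ctgov")
  if ("drksid" %in% names(history)) return("drks")
  stop("not a history table: no `nctid` or `drksid` column", call. = FALSE)
}

# Name of the status column carrying the Error sentinel.
status_column <- function(registry) {
  if (registry == "ctgov") "overall_status" else "recruitment_status"
}

id_column <- function(registry) {
  if (registry == "ctgov") "nctid" else "drksid"
}

#' Validate trial identifiers
#'
#' ClinicalTrials.gov identifiers match `NCT[0-9]{8}`; DRKS identifiers match
#' `DRKS[0-9]{8}`.
#'
#' @param ids Character vector of trial identifiers.
#' @param registry `"ctgov"` or `"drks"`.
#' @return Logical vector, `TRUE` where the id is well formed.
#' @export
#' @examples
#' is_trial_id(c("NCT01234567", "DRKS00001234"), "ctgov")
is_trial_id <- function(ids, registry = c("ctgov", "drks")) {
  registry <- match.arg(registry)
  pattern <- if (registry == "ctgov") "^NCT[0-9]{8}$" else "^DRKS[0-9]{8}$"
  grepl(pattern, ids)
}

# Infer the registry of a vector of ids; error if mixed or unrecognized.
infer_registry <- function(ids) {
  if (length(ids) == 0) stop("no trial ids supplied", call. = FALSE)
  ctgov <- is_trial_id(ids, "ctgov")
  drks <- is_trial_id(ids, "drks")
  if (all(ctgov)) return("ctgov")
  if (all(drks)) return("drks")
  bad <- ids[!(ctgov | drks)]
  if (length(bad) > 0) {
    stop(
      "unrecognized trial id(s): ", paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  stop("trial ids mix registries; supply one registry per download",
    call. = FALSE
  )
}

#' Empty history table
#'
#' @param registry `"ctgov"` or `"drks"`.
#' @return Zero-row tibble with the full history schema.
#' @export
empty_history <- function(registry = c("ctgov", "drks")) {
  registry <- match.arg(registry)
  cols <- history_columns(registry)
  types <- history_col_types(registry)
  out <- lapply(cols, function(col) {
    if (col %in% types$integer) integer(0) else character(0)
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' Encode a nested registry structure as canonical JSON
#'
#' Nested registry structures (criteria lines, outcome-measure rows, contact
#' rows, sponsor rows) are stored in history tables as JSON strings. The
#' encoding is canonical — keys sorted alphabetically, compact separators, no
#' insignificant whitespace — so that two cells are byte-equal if and only if
#' they encode structurally equal values. Downstream change detection
#' ([outcome_change_runs()]) relies on this: an edit as small as one
#' whitespace character inside a value yields a different encoding.
#'
#' @param x A character vector (encoded as a JSON array of strings) or a data
#'   frame / list of records with identical fields (encoded as a JSON array
#'   of objects). `NULL` encodes the absent structure and returns `NA`.
#' @return Length-1 character JSON, or `NA_character_` for `NULL` input.
#' @seealso [decode_nested()]
#' @export
#' @examples
#' encode_nested(c("Inclusion Criteria:", "- age over 18"))
#' encode_nested(data.frame(label = "Lead Sponsor:", content = "University X"))
encode_nested <- function(x) {
  if (is.null(x)) return(NA_character_)
  if (is.data.frame(x)) {
    if (nrow(x) == 0 || ncol(x) == 0) return("[]")
    x <- x[, sort(names(x)), drop = FALSE]
    for (col in names(x)) {
      if (!is.character(x[[col]])) {
        stop("non-text column in nested structure: ", col, call. = FALSE)
      }
    }
    return(as.character(
      jsonlite::toJSON(x, dataframe = "rows", na = "null")
    ))
  }
  if (is.list(x)) {
    if (length(x) == 0) return("[]")
    keysets <- unique(lapply(x, function(r) sort(names(r))))
    if (length(keysets) > 1) {
      stop("records in one nested structure must share one key set",
        call. = FALSE
      )
    }
    df <- do.call(rbind, lapply(x, function(r) {
      as.data.frame(r[sort(names(r))], stringsAsFactors = FALSE)
    }))
    return(encode_nested(df))
  }
  if (is.character(x)) {
    if (anyNA(x)) stop("NA line in nested structure", call. = FALSE)
    return(as.character(jsonlite::toJSON(x)))
  }
  stop("cannot encode object of class ", paste(class(x), collapse = "/"),
    call. = FALSE
  )
}

#' Decode a canonical JSON cell back to its tabular structure
#'
#' Inverse of [encode_nested()]: a JSON array of strings decodes to a
#' character vector, an array of objects to a tibble (missing sub-fields
#' become `NA`).
#'
#' @param json Length-1 character JSON string (or `NA`).
#' @return Character vector, tibble, or `NULL` for `NA` input.
#' @export
decode_nested <- function(json) {
  if (length(json) != 1) stop("decode_nested() expects one JSON string")
  if (is.na(json)) return(NULL)
  out <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (is.data.frame(out)) return(tibble::as_tibble(out))
  if (length(out) == 0) return(character(0))
  out
}

#' Write a history table to CSV
#'
#' RFC-4180 CSV, UTF-8, header row, columns in the order of
#' [history_columns()]. Nested fields are stored as their canonical JSON
#' strings; missing values are written as empty cells (distinct from the
#' literal text `"NA"`, which registry free text may legitimately contain).
#' Writing, re-reading with [read_history_csv()] and writing again produces a
#' byte-identical file.
#'
#' @param history History table (tibble) in the schema of its registry.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  registry <- history_registry(history)
  cols <- history_columns(registry)
  missing_cols <- setdiff(cols, names(history))
  if (length(missing_cols) > 0) {
    stop("history table lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  ok <- tryCatch(
    {
      readr::write_csv(history[, cols], path, na = "")
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) {
    stop("cannot write history CSV to ", path, ": ", conditionMessage(ok),
      call. = FALSE
    )
  }
  invisible(path)
}

#' Read a history table from CSV
#'
#' Inverse of [write_history_csv()]. The registry is detected from the header
#' (`nctid` vs `drksid`). Unknown extra columns are dropped with a warning
#' (tolerant reader); missing schema columns are an error naming the column;
#' an empty file is a schema error. Empty cells are read as missing; the
#' literal text `"NA"` is kept as text.
#'
#' @param path Path to a history CSV.
#' @return History table tibble.
#' @export
read_history_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readr::read_lines(path, n_max = 1)
  if (length(header) == 0 || !nzchar(header)) {
    stop("empty history file (no header): ", path, call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE
  )
  registry <- history_registry(raw)
  cols <- history_columns(registry)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("history CSV lacks schema column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(names(raw), cols)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  out <- raw[, cols]
  for (col in history_col_types(registry)$integer) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}

# Is a history row an error-sentinel row?
is_error_row <- function(history, registry = history_registry(history)) {
  status <- history[[status_column(registry)]]
  !is.na(status) & status == ERROR_SENTINEL
}
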