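# Parser for the classic ClinicalTrials.gov history dialect.
#
# Extraction is declarative: each simple data point is one (CSS selector,
# regex-with-one-capture-group) rule; nested tables (criteria, outcome
# measures, contacts, sponsors) have dedicated table walkers and are encoded
# as canonical JSON. Element text keeps internal whitespace untouched (change
# detection must see single-character whitespace edits) and only strips
# leading/trailing whitespace.

# Parse html text to an xml document, passing documents through.
as_html_doc <- function(html) {
  if (inherits(html, "xml_document")) return(html)
  xml2::read_html(html, encoding = "UTF-8")
}

# Text of a node with ends trimmed, internal whitespace preserved.
node_text <- function(node) {
  trimws(xml2::xml_text(node))
}

#' Extraction rules for ClinicalTrials.gov version pages
#'
#' The declarative table of CSS selectors and regular expressions that drives
#' [parse_ctgov_version()]. Simple fields carry a regex with exactly one
#' capture group; fields extracted by walking an HTML table are marked with
#' regex `"NESTED"`.
#'
#' @return Tibble with columns `field`, `css`, `regex`.
#' @export
ctgov_extraction_rules <- function() {
  rules <- tibble::tribble(
    ~field, ~css, ~regex,
    "overall_status", "#StudyStatusBody", "Overall Status: ([A-Za-z, ]+)",
    "enrolment", "#StudyDesignBody", "Enrollment: ([A-Za-z0-9 \\[\\]]+)",
    "study_start_date", "#StudyStatusBody", "Study Start: ([A-Za-z0-9, ]+)",
    "primary_completion_date", "#StudyStatusBody",
    "Primary Completion: ([A-Za-z0-9, \\[\\]]+)",
    "primary_completion_date_type", "#StudyStatusBody", "(\\[[A-Za-z]+\\])",
    "min_age", "#EligibilityBody", "Minimum Age: ([0-9]+) Years",
    "max_age", "#EligibilityBody", "Maximum Age: ([0-9]+) Years",
    "sex", "#EligibilityBody", "Sex: ([A-Za-z]+)",
    "gender_based", "#EligibilityBody", "Gender Based: ([A-Za-z]+)",
    "accepts_healthy_volunteers", "#EligibilityBody",
    "Accepts Healthy Volunteers: ([A-Za-z]+)",
    "criteria", "#EligibilityBody", "NESTED",
    "outcome_measures", "#ProtocolOutcomeMeasuresBody", "NESTED",
    "contacts", "#ContactsLocationsBody", "NESTED",
    "sponsors", "#SponsorCollaboratorsBody", "NESTED"
  )
  validate_rules(rules)
  rules
}

# Configuration-time validation: selectors and regexes must be usable and
# every non-nested regex must have at most one capture group (a group-less
# regex extracts its whole match, as for the DRKS enrolment and date rules).
validate_rules <- function(rules) {
  for (i in seq_len(nrow(rules))) {
    regex <- rules$regex[i]
    if (identical(regex, "NESTED")) next
    n_groups <- stringr::str_count(regex, stringr::fixed("(")) -
      stringr::str_count(regex, stringr::fixed("\\("))
    ok <- tryCatch(
      {
        stringr::str_match("probe", regex)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      stop("invalid extraction regex for field ", rules$field[i],
        call. = FALSE
      )
    }
    if (!n_groups %in% c(0L, 1L)) {
      stop("extraction regex for field ", rules$field[i],
        " must contain at most one capture group",
        call. = FALSE
      )
    }
  }
  invisible(rules)
}

# Candidate cells for a rule: descendant table cells or list items of the
# selected element(s), falling back to the elements themselves (DRKS bullet
# elements have no cell descendants).
rule_cells <- function(doc, css) {
  nodes <- rvest::html_elements(doc, css)
  if (length(nodes) == 0) return(nodes)
  cells <- rvest::html_elements(nodes, "td, th")
  if (length(cells) == 0) nodes else cells
}

#' Extract one simple data point with a selector + regex rule
#'
#' Applies `rule$regex` (search semantics, unanchored) to the text of each
#' cell under the elements matched by `rule$css`, in document order, and
#' returns the first capture group of the first match. Returns `NA` when no
#' element or no cell text matches.
#'
#' @param html HTML text or a parsed `xml_document`.
#' @param rule One-row subset of an extraction-rules table (or a list with
#'   `css` and `regex`).
#' @return Length-1 character, or `NA_character_`.
#' @export
#' @examples
#' page <- "<table id='StudyStatusBody'>
#'   <tr><td>Overall Status: Recruiting</td></tr></table>"
#' rule <- list(css = "#StudyStatusBody", regex = "Overall Status: ([A-Za-z, ]+)")
#' extract_field(page, rule)
extract_field <- function(html, rule) {
  if (identical(rule$regex, "NESTED")) {
    stop("extract_field() does not handle NESTED rules", call. = FALSE)
  }
  doc <- as_html_doc(html)
  cells <- rule_cells(doc, rule$css)
  if (length(cells) == 0) return(NA_character_)
  texts <- vapply(cells, node_text, character(1))
  m <- stringr::str_match(texts, rule$regex)
  # group-less rules (DRKS enrolment, DRKS dates) extract the whole match
  col <- if (ncol(m) >= 2) 2L else 1L
  hits <- which(!is.na(m[, col]))
  if (length(hits) == 0) return(NA_character_)
  trimws(m[hits[1], col])
}

# Find the data-cell column of a history-index table by its header text;
# returns the cells of that column (in row order) or NULL.
index_column_cells <- function(doc, header_text) {
  tables <- rvest::html_elements(doc, "table")
  for (tbl in tables) {
    rows <- rvest::html_elements(tbl, "tr")
    if (length(rows) < 1) next
    header <- vapply(
      rvest::html_elements(rows[[1]], "th, td"), node_text, character(1)
    )
    idx <- which(header == header_text)
    if (length(idx) == 0) next
    out <- character(0)
    for (row in rows[-1]) {
      cells <- rvest::html_elements(row, "td, th")
      if (length(cells) < idx[1]) next
      out <- c(out, node_text(cells[[idx[1]]]))
    }
    return(out)
  }
  NULL
}

#' Parse a ClinicalTrials.gov history index page into version dates
#'
#' Reads the "Submitted Date" column of the study-record-versions table and
#' returns one ISO-8601 date per registry entry version, earliest first.
#' Malformed input raises a parse error rather than returning partial output.
#'
#' @param html HTML text or parsed document of the history index page.
#' @return Character vector of ISO-8601 dates, one per version.
#' @export
parse_ctgov_dates <- function(html) {
  doc <- as_html_doc(html)
  cells <- index_column_cells(doc, "Submitted Date")
  if (is.null(cells)) {
    stop("no study-record-versions table with a \"Submitted Date\" column",
      call. = FALSE
    )
  }
  vapply(cells, function(cell) {
    parsed <- normalize_ctgov_date(cell)
    if (parsed$precision != "day") {
      stop("submitted date not day-precise: \"", cell, "\"", call. = FALSE)
    }
    parsed$date
  }, character(1), USE.NAMES = FALSE)
}

# Split a table cell into text lines at <br> boundaries; line ends trimmed,
# internal whitespace kept; empty lines dropped.
cell_lines <- function(cell) {
  pieces <- character(0)
  current <- ""
  walk <- function(node) {
    for (child in xml2::xml_contents(node)) {
      name <- xml2::xml_name(child)
      if (name == "br") {
        pieces <<- c(pieces, current)
        current <<- ""
      } else if (name == "text") {
        current <<- paste0(current, xml2::xml_text(child))
      } else {
        walk(child)
      }
    }
  }
  walk(cell)
  pieces <- c(pieces, current)
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Parse the eligibility criteria cell
#'
#' The criteria are the lines of the `#EligibilityBody` cell that immediately
#' follows the cell labelled `"Criteria:"`, JSON-encoded in order. An absent
#' label yields `NA` (missing, not an error); a blank cell yields `"[]"`.
#'
#' @inheritParams extract_field
#' @return Canonical JSON array of text lines, or `NA_character_`.
#' @export
parse_ctgov_criteria <- function(html) {
  doc <- as_html_doc(html)
  body <- rvest::html_elements(doc, "#EligibilityBody")
  if (length(body) == 0) return(NA_character_)
  for (row in rvest::html_elements(body, "tr")) {
    cells <- rvest::html_elements(row, "td, th")
    for (i in seq_along(cells)) {
      if (node_text(cells[[i]]) == "Criteria:" && i < length(cells)) {
        return(encode_nested(cell_lines(cells[[i + 1]])))
      }
    }
  }
  NA_character_
}

# Walk a two-column body table into (label, content) rows.
two_column_rows <- function(body) {
  out <- list()
  for (row in rvest::html_elements(body, "tr")) {
    cells <- rvest::html_elements(row, "td, th")
    if (length(cells) < 2) next
    out[[length(out) + 1]] <- list(
      label = node_text(cells[[1]]),
      content = node_text(cells[[2]])
    )
  }
  out
}

#' Parse the outcome-measures table
#'
#' Rows of `#ProtocolOutcomeMeasuresBody` become `{section, label, content}`
#' records. Section headings are rows whose second cell is textless; they are
#' consumed as headings (not emitted), and each data row's `section` is the
#' nearest preceding heading.
#'
#' @inheritParams extract_field
#' @return Canonical JSON array of records, or `NA_character_` when the table
#'   is absent.
#' @export
parse_ctgov_outcome_measures <- function(html) {
  doc <- as_html_doc(html)
  body <- rvest::html_elements(doc, "#ProtocolOutcomeMeasuresBody")
  if (length(body) == 0) return(NA_character_)
  section <- NA_character_
  records <- list()
  for (row in two_column_rows(body)) {
    if (!nzchar(row$content)) {
      section <- row$label
    } else {
      records[[length(records) + 1]] <- list(
        section = section, label = row$label, content = row$content
      )
    }
  }
  encode_nested(records)
}

#' Parse the contacts table
#'
#' Rows of `#ContactsLocationsBody` strictly before the row labelled
#' `"Locations:"` become `{label, content}` records. When no `"Locations:"`
#' row is present all rows are included, with a warning.
#'
#' @inheritParams extract_field
#' @return Canonical JSON array of records, or `NA_character_` when the table
#'   is absent.
#' @export
parse_ctgov_contacts <- function(html) {
  doc <- as_html_doc(html)
  body <- rvest::html_elements(doc, "#ContactsLocationsBody")
  if (length(body) == 0) return(NA_character_)
  rows <- two_column_rows(body)
  labels <- vapply(rows, function(r) r$label, character(1))
  boundary <- which(labels == "Locations:")
  if (length(boundary) == 0) {
    if (length(rows) > 0) {
      warning("no \"Locations:\" row in contacts table; including all rows",
        call. = FALSE
      )
    }
  } else {
    rows <- rows[seq_len(boundary[1] - 1)]
  }
  encode_nested(rows)
}

#' Parse the sponsors table
#'
#' All rows of `#SponsorCollaboratorsBody` become `{label, content}` records
#' in document order.
#'
#' @inheritParams extract_field
#' @return Canonical JSON array of records, or `NA_character_` when the table
#'   is absent.
#' @export
parse_ctgov_sponsors <- function(html) {
  doc <- as_html_doc(html)
  body <- rvest::html_elements(doc, "#SponsorCollaboratorsBody")
  if (length(body) == 0) return(NA_character_)
  encode_nested(two_column_rows(body))
}

# Sentinel record: identification kept, status = Error, all else missing.
ctgov_error_record <- function(nctid, version_number, version_date) {
  ctgov_record(
    nctid = nctid,
    version_number = as.integer(version_number),
    version_date = as.character(version_date),
    overall_status = ERROR_SENTINEL
  )
}

# One-row ctgov history tibble; unspecified fields are missing.
ctgov_record <- function(...) {
  given <- list(...)
  cols <- history_columns("ctgov")
  stopifnot(all(names(given) %in% cols))
  row <- lapply(cols, function(col) {
    if (col %in% names(given)) {
      given[[col]]
    } else if (col == "version_number") {
      NA_integer_
    } else {
      NA_character_
    }
  })
  names(row) <- cols
  tibble::as_tibble(row)
}

#' Parse one ClinicalTrials.gov version page into a history row
#'
#' Extracts all 16 data points (overall status, enrolment, start date + its
#' precision, primary completion date + its precision + its type, minimum and
#' maximum age, sex, gender based, accepts healthy volunteers, inclusion
#' criteria, outcome measures, contacts, sponsors) using
#' [ctgov_extraction_rules()]. The function is total: any input yields either
#' a populated row (fields individually `NA` when absent from the page) or,
#' on unrecoverable failure — unparseable document or a page with no
#' `#StudyStatusBody` — a sentinel row whose `overall_status` is `"Error"`,
#' so that a bulk download loop can continue and mark the row for re-download.
#'
#' @inheritParams extract_field
#' @param nctid Trial identifier (`NCT` + 8 digits).
#' @param version_number 1-based version number (1 = earliest).
#' @param version_date ISO-8601 date the version was submitted.
#' @return One-row tibble in the ClinicalTrials.gov history schema.
#' @export
parse_ctgov_version <- function(html, nctid, version_number, version_date) {
  tryCatch(
    {
      doc <- as_html_doc(html)
      if (length(rvest::html_elements(doc, "#StudyStatusBody")) == 0) {
        stop("no #StudyStatusBody table", call. = FALSE)
      }
      rules <- ctgov_extraction_rules()
      get_rule <- function(field) rules[rules$field == field, ]
      simple <- function(field) extract_field(doc, get_rule(field))

      start_raw <- simple("study_start_date")
      start <- list(date = NA_character_, precision = NA_character_)
      if (!is.na(start_raw)) start <- normalize_ctgov_date(start_raw)

      pcd_raw <- simple("primary_completion_date")
      pcd <- list(date = NA_character_, precision = NA_character_)
      if (!is.na(pcd_raw)) {
        # the capture includes the bracketed type token; drop it before
        # date parsing (the token is captured separately below)
        pcd <- normalize_ctgov_date(
          trimws(stringr::str_remove(pcd_raw, "\\s*\\[[A-Za-z]+\\]"))
        )
      }
      pcd_type <- simple("primary_completion_date_type")
      if (!is.na(pcd_type)) {
        # stored without brackets for cleaner downstream comparison
        pcd_type <- stringr::str_remove_all(pcd_type, "[\\[\\]]")
      }

      ctgov_record(
        nctid = nctid,
        version_number = as.integer(version_number),
        version_date = version_date,
        overall_status = simple("overall_status"),
        enrolment = simple("enrolment"),
        study_start_date = start$date,
        start_date_precision = start$precision,
        primary_completion_date = pcd$date,
        primary_completion_date_precision = pcd$precision,
        primary_completion_date_type = pcd_type,
        min_age = simple("min_age"),
        max_age = simple("max_age"),
        sex = simple("sex"),
        gender_based = simple("gender_based"),
        accepts_healthy_volunteers = simple("accepts_healthy_volunteers"),
        criteria = parse_ctgov_criteria(doc),
        outcome_measures = parse_ctgov_outcome_measures(doc),
        contacts = parse_ctgov_contacts(doc),
        sponsors = parse_ctgov_sponsors(doc)
      )
    },
    error = function(e) {
      ctgov_error_record(nctid, version_number, version_date)
    }
  )
}
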