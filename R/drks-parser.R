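# Parser for the DRKS.de change-history dialect.
#
# DRKS version pages are bullet lists rather than labelled tables: simple
# fields live in <li> elements (li.state, li.targetSize, ...), nested fields
# in block elements (.inclusionAdd, .exclusion, p.primaryEndpoint,
# p.secondaryEndpoints) and contact records in ul.addresses li.address
# bullets. Dates use the slash dialect YYYY/MM/DD and are always day-precise.

#' Extraction rules for DRKS.de version pages
#'
#' Declarative selector/regex table driving [parse_drks_version()]; nested
#' fields are marked with regex `"NESTED"`.
#'
#' @return Tibble with columns `field`, `css`, `regex`.
#' @export
drks_extraction_rules <- function() {
  rules <- tibble::tribble(
    ~field, ~css, ~regex,
    "recruitment_status", "li.state", "Recruitment Status: ([A-Za-z, -]+)",
    "enrolment", "li.targetSize", "[0-9]+",
    "enrolment_type", "li.targetSize", "Planned/Actual: ([A-Za-z]+)",
    "start_date", "li.schedule", "[0-9]{4}/[0-9]{2}/[0-9]{2}",
    "closing_date", "li.deadline", "[0-9]{4}/[0-9]{2}/[0-9]{2}",
    "min_age", "li.minAge", "Minimum Age: ([A-Za-z0-9 ]+)",
    "max_age", "li.maxAge", "Maximum Age: ([A-Za-z0-9 ]+)",
    "gender", "li.gender", "Gender: ([A-Za-z ]+)",
    "inclusion_criteria_additional", ".inclusionAdd", "NESTED",
    "exclusion_criteria", ".exclusion", "NESTED",
    "primary_outcomes", "p.primaryEndpoint", "NESTED",
    "secondary_outcomes", "p.secondaryEndpoints", "NESTED",
    "contacts", "ul.addresses li.address", "NESTED"
  )
  validate_rules(rules)
  rules
}

#' Parse a DRKS.de change-history page into version dates
#'
#' Reads the "Date" column of the published-versions table and returns one
#' ISO-8601 date per published version, earliest first (sorted defensively,
#' whatever order the page renders).
#'
#' @param html HTML text or parsed document of the change-history page.
#' @return Character vector of ISO-8601 dates, one per version.
#' @export
parse_drks_dates <- function(html) {
  doc <- as_html_doc(html)
  cells <- index_column_cells(doc, "Date")
  if (is.null(cells)) {
    stop("no published-versions table with a \"Date\" column", call. = FALSE)
  }
  if (length(cells) == 0) {
    stop("published-versions table has no version rows", call. = FALSE)
  }
  sort(vapply(cells, normalize_drks_date, character(1), USE.NAMES = FALSE))
}

#' Parse one nested DRKS text block as JSON lines
#'
#' For the four nested text fields (selectors `.inclusionAdd`, `.exclusion`,
#' `p.primaryEndpoint`, `p.secondaryEndpoints`): the matched element's text
#' becomes a JSON array with one element per line, order and internal
#' whitespace preserved. No match yields `NA` (missing).
#'
#' @inheritParams extract_field
#' @param selector One of the four nested-field CSS selectors.
#' @return Canonical JSON array of lines, or `NA_character_`.
#' @export
parse_drks_nested <- function(html, selector) {
  allowed <- c(
    ".inclusionAdd", ".exclusion", "p.primaryEndpoint", "p.secondaryEndpoints"
  )
  if (!selector %in% allowed) {
    stop("unknown DRKS nested selector: ", selector, call. = FALSE)
  }
  doc <- as_html_doc(html)
  nodes <- rvest::html_elements(doc, selector)
  if (length(nodes) == 0) return(NA_character_)
  encode_nested(cell_lines(nodes[[1]]))
}

# Text of a node excluding its <label> child, ends trimmed.
text_excluding_label <- function(node) {
  parts <- character(0)
  for (child in xml2::xml_contents(node)) {
    if (xml2::xml_name(child) == "label") next
    parts <- c(parts, xml2::xml_text(child))
  }
  out <- trimws(paste(parts, collapse = ""))
  if (nzchar(out)) out else NA_character_
}

#' Parse DRKS contact addresses
#'
#' Each `ul.addresses li.address` bullet yields one record with fields
#' `label` (from the bullet's `<label>` node), `affiliation` (from
#' `li.address-affiliation`) and `telephone`, `fax`, `email`, `url` (from
#' `.address-telephone`, `.address-fax`, `.address-email`, `.address-url`,
#' excluding each sub-element's own label text). Absent sub-fields are
#' missing (`null` in the JSON).
#'
#' @inheritParams extract_field
#' @return Canonical JSON array of records, or `NA_character_` when the
#'   addresses list is absent.
#' @export
parse_drks_contacts <- function(html) {
  doc <- as_html_doc(html)
  bullets <- rvest::html_elements(doc, "ul.addresses li.address")
  if (length(bullets) == 0) return(NA_character_)
  sub_field <- function(bullet, css) {
    node <- rvest::html_elements(bullet, css)
    if (length(node) == 0) return(NA_character_)
    text_excluding_label(node[[1]])
  }
  records <- lapply(bullets, function(bullet) {
    # the address's own label is its direct <label> child; sub-bullets carry
    # their own labels, which must not be picked up here
    label_node <- xml2::xml_find_first(bullet, "./label")
    list(
      label = if (!inherits(label_node, "xml_missing")) {
        node_text(label_node)
      } else {
        NA_character_
      },
      affiliation = {
        aff <- rvest::html_elements(bullet, "li.address-affiliation")
        if (length(aff) > 0) node_text(aff[[1]]) else NA_character_
      },
      telephone = sub_field(bullet, ".address-telephone"),
      fax = sub_field(bullet, ".address-fax"),
      email = sub_field(bullet, ".address-email"),
      url = sub_field(bullet, ".address-url")
    )
  })
  records <- lapply(records, function(r) lapply(r, as.character))
  encode_nested(records)
}

# Sentinel record for a failed DRKS version download/parse.
drks_error_record <- function(drksid, version_number, version_date) {
  drks_record(
    drksid = drksid,
    version_number = as.integer(version_number),
    version_date = as.character(version_date),
    recruitment_status = ERROR_SENTINEL
  )
}

# One-row DRKS history tibble; unspecified fields are missing.
drks_record <- function(...) {
  given <- list(...)
  cols <- history_columns("drks")
  stopifnot(all(names(given) %in% cols))
  ints <- history_col_types("drks")$integer
  row <- lapply(cols, function(col) {
    if (col %in% names(given)) {
      given[[col]]
    } else if (col %in% ints) {
      NA_integer_
    } else {
      NA_character_
    }
  })
  names(row) <- cols
  tibble::as_tibble(row)
}

#' Parse one DRKS.de version page into a history row
#'
#' Extracts all 13 data points (recruitment status, start date, closing date,
#' enrolment, enrolment type, minimum and maximum age, gender, additional
#' inclusion criteria, exclusion criteria, primary outcomes, secondary
#' outcomes, contacts) using [drks_extraction_rules()]. Total like its
#' ClinicalTrials.gov counterpart: unrecoverable failure — unparseable
#' document or a page with no `li.state` bullet — yields a sentinel row with
#' `recruitment_status` `"Error"`.
#'
#' @inheritParams extract_field
#' @param drksid Trial identifier (`DRKS` + 8 digits).
#' @param version_number 1-based version number (1 = earliest).
#' @param version_date ISO-8601 date of the published version.
#' @return One-row tibble in the DRKS history schema.
#' @export
parse_drks_version <- function(html, drksid, version_number, version_date) {
  tryCatch(
    {
      doc <- as_html_doc(html)
      if (length(rvest::html_elements(doc, "li.state")) == 0) {
        stop("no li.state element", call. = FALSE)
      }
      rules <- drks_extraction_rules()
      simple <- function(field) {
        extract_field(doc, rules[rules$field == field, ])
      }
      start_raw <- simple("start_date")
      closing_raw <- simple("closing_date")
      enrol_raw <- simple("enrolment")
      drks_record(
        drksid = drksid,
        version_number = as.integer(version_number),
        version_date = as.character(version_date),
        recruitment_status = simple("recruitment_status"),
        start_date = if (is.na(start_raw)) {
          NA_character_
        } else {
          normalize_drks_date(start_raw)
        },
        closing_date = if (is.na(closing_raw)) {
          NA_character_
        } else {
          normalize_drks_date(closing_raw)
        },
        enrolment = if (is.na(enrol_raw)) {
          NA_integer_
        } else {
          as.integer(enrol_raw)
        },
        enrolment_type = simple("enrolment_type"),
        min_age = simple("min_age"),
        max_age = simple("max_age"),
        gender = simple("gender"),
        inclusion_criteria_additional =
          parse_drks_nested(doc, ".inclusionAdd"),
        exclusion_criteria = parse_drks_nested(doc, ".exclusion"),
        primary_outcomes = parse_drks_nested(doc, "p.primaryEndpoint"),
        secondary_outcomes = parse_drks_nested(doc, "p.secondaryEndpoints"),
        contacts = parse_drks_contacts(doc)
      )
    },
    error = function(e) {
      drks_error_record(drksid, version_number, version_date)
    }
  )
}
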