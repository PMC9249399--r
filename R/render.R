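# Rendering ground-truth records as registry-dialect HTML.
#
# Each renderer is the inverse of the corresponding parser over the fixture
# dialect: parse(render(record)) must reproduce the record field-for-field.
# Pages carry a filler <head> so that truncation corruption reliably destroys
# the parsed substructure.

html_escape <- function(text) {
  text <- gsub("&", "&amp;", text, fixed = TRUE)
  text <- gsub("<", "&lt;", text, fixed = TRUE)
  gsub(">", "&gt;", text, fixed = TRUE)
}

# Join lines with <br/> inside one cell/element.
lines_html <- function(lines) {
  paste(vapply(lines, html_escape, character(1)), collapse = "<br/>")
}

page_head <- function(title) {
  paste0(
    "<html><head><title>", html_escape(title), "</title>\n",
    "<meta charset=\"utf-8\"/>\n",
    "<!-- synthetic registry fixture page: emulates the parsed element ",
    "substructure of the registry dialect, not its visual chrome -->\n",
    "</head><body>\n"
  )
}

two_col_row <- function(label, content) {
  paste0(
    "<tr><td>", html_escape(label), "</td><td>", html_escape(content),
    "</td></tr>\n"
  )
}

# --- ClinicalTrials.gov dialect ---------------------------------------------

render_ctgov_index_page <- function(id, dates) {
  rows <- vapply(seq_along(dates), function(i) {
    paste0(
      "<tr><td>", i, "</td><td>",
      html_escape(format_ctgov_date(dates[i], "day")), "</td></tr>\n"
    )
  }, character(1))
  paste0(
    page_head(paste("History of changes for", id)),
    "<table id=\"HistoryTable\">\n",
    "<tr><th>Version</th><th>Submitted Date</th></tr>\n",
    paste(rows, collapse = ""),
    "</table>\n</body></html>\n"
  )
}

render_ctgov_version_page <- function(record) {
  status_rows <- paste0(
    two_col_row("Status", paste0("Overall Status: ", record$overall_status)),
    if (!is.na(record$study_start_date)) {
      two_col_row(
        "Start",
        paste0(
          "Study Start: ",
          format_ctgov_date(
            record$study_start_date, record$start_date_precision
          )
        )
      )
    },
    if (!is.na(record$primary_completion_date)) {
      two_col_row(
        "Completion",
        paste0(
          "Primary Completion: ",
          format_ctgov_date(
            record$primary_completion_date,
            record$primary_completion_date_precision
          ),
          " [", record$primary_completion_date_type, "]"
        )
      )
    }
  )

  design_rows <- two_col_row(
    "Enrollment", paste0("Enrollment: ", record$enrolment)
  )

  eligibility_rows <- paste0(
    two_col_row("Ages", paste0("Minimum Age: ", record$min_age, " Years")),
    two_col_row("", paste0("Maximum Age: ", record$max_age, " Years")),
    two_col_row("Sex", paste0("Sex: ", record$sex)),
    two_col_row("", paste0("Gender Based: ", record$gender_based)),
    two_col_row(
      "Volunteers",
      paste0(
        "Accepts Healthy Volunteers: ", record$accepts_healthy_volunteers
      )
    ),
    if (!is.na(record$criteria)) {
      paste0(
        "<tr><td>Criteria:</td><td>",
        lines_html(decode_nested(record$criteria)),
        "</td></tr>\n"
      )
    }
  )

  outcome_rows <- ""
  if (!is.na(record$outcome_measures)) {
    measures <- decode_nested(record$outcome_measures)
    section <- NA_character_
    parts <- character(0)
    if (!is.null(measures) && is.data.frame(measures) && nrow(measures) > 0) {
      for (i in seq_len(nrow(measures))) {
        if (is.na(section) || measures$section[i] != section) {
          section <- measures$section[i]
          parts <- c(parts, two_col_row(section, ""))
        }
        parts <- c(
          parts, two_col_row(measures$label[i], measures$content[i])
        )
      }
    }
    outcome_rows <- paste(parts, collapse = "")
  }

  contact_rows <- ""
  if (!is.na(record$contacts)) {
    contacts <- decode_nested(record$contacts)
    parts <- character(0)
    if (!is.null(contacts) && is.data.frame(contacts) && nrow(contacts) > 0) {
      for (i in seq_len(nrow(contacts))) {
        parts <- c(
          parts, two_col_row(contacts$label[i], contacts$content[i])
        )
      }
    }
    # locations after the divider are render-only chrome: the parser must
    # exclude everything from the "Locations:" row onward
    parts <- c(
      parts,
      two_col_row("Locations:", ""),
      two_col_row("Location:", "Study Site 1, Example City")
    )
    contact_rows <- paste(parts, collapse = "")
  }

  sponsor_rows <- ""
  if (!is.na(record$sponsors)) {
    sponsors <- decode_nested(record$sponsors)
    parts <- character(0)
    if (!is.null(sponsors) && is.data.frame(sponsors) && nrow(sponsors) > 0) {
      for (i in seq_len(nrow(sponsors))) {
        parts <- c(
          parts, two_col_row(sponsors$label[i], sponsors$content[i])
        )
      }
    }
    sponsor_rows <- paste(parts, collapse = "")
  }

  paste0(
    page_head(paste0(
      record$nctid, " version ", record$version_number, " (",
      record$version_date, ")"
    )),
    "<table id=\"StudyStatusBody\">\n", status_rows, "</table>\n",
    "<table id=\"StudyDesignBody\">\n", design_rows, "</table>\n",
    "<table id=\"EligibilityBody\">\n", eligibility_rows, "</table>\n",
    "<table id=\"ProtocolOutcomeMeasuresBody\">\n", outcome_rows,
    "</table>\n",
    "<table id=\"ContactsLocationsBody\">\n", contact_rows, "</table>\n",
    "<table id=\"SponsorCollaboratorsBody\">\n", sponsor_rows, "</table>\n",
    "</body></html>\n"
  )
}

#' Render ClinicalTrials.gov fixture pages for a ground truth
#'
#' Renders one history-index page per trial (with a "Submitted Date" column)
#' and one version page per record, each containing every extraction-table
#' element with text formatted to satisfy the extraction regexes.
#'
#' @param truth A list with a ClinicalTrials.gov `records` history table.
#' @return List with `pages` (`"<id>_<version>"` -> HTML) and `index_pages`
#'   (`"<id>"` -> HTML).
#' @export
render_ctgov <- function(truth) {
  records <- truth$records
  pages <- list()
  index_pages <- list()
  for (id in unique(records$nctid)) {
    rows <- records[records$nctid == id, ]
    index_pages[[id]] <- render_ctgov_index_page(id, rows$version_date)
    for (i in seq_len(nrow(rows))) {
      key <- paste0(id, "_", rows$version_number[i])
      pages[[key]] <- render_ctgov_version_page(rows[i, ])
    }
  }
  list(pages = pages, index_pages = index_pages)
}

# --- DRKS dialect -----------------------------------------------------------

render_drks_index_page <- function(id, dates) {
  rows <- vapply(dates, function(d) {
    paste0("<tr><td>", format_drks_date(d), "</td></tr>\n")
  }, character(1))
  paste0(
    page_head(paste("Change history for", id)),
    "<table class=\"versionsTable\">\n",
    "<tr><th>Date</th></tr>\n",
    paste(rows, collapse = ""),
    "</table>\n</body></html>\n"
  )
}

drks_bullet <- function(class, text) {
  paste0("<li class=\"", class, "\">", html_escape(text), "</li>\n")
}

render_drks_address <- function(contact) {
  sub_bullet <- function(class, label, value) {
    if (is.na(value)) return("")
    paste0(
      "<li class=\"", class, "\"><label>", html_escape(label),
      "</label> ", html_escape(value), "</li>\n"
    )
  }
  paste0(
    "<li class=\"address\"><label>", html_escape(contact$label),
    "</label>\n<ul>\n",
    if (!is.na(contact$affiliation)) {
      paste0(
        "<li class=\"address-affiliation\">",
        html_escape(contact$affiliation), "</li>\n"
      )
    },
    sub_bullet("address-telephone", "Telephone:", contact$telephone),
    sub_bullet("address-fax", "Fax:", contact$fax),
    sub_bullet("address-email", "E-mail:", contact$email),
    sub_bullet("address-url", "URL:", contact$url),
    "</ul></li>\n"
  )
}

render_drks_version_page <- function(record) {
  nested_block <- function(tag, class, json) {
    if (is.na(json)) return("")
    lines <- decode_nested(json)
    paste0(
      "<", tag, " class=\"", class, "\">", lines_html(lines),
      "</", tag, ">\n"
    )
  }

  addresses <- ""
  if (!is.na(record$contacts)) {
    contacts <- decode_nested(record$contacts)
    parts <- character(0)
    if (!is.null(contacts) && is.data.frame(contacts) && nrow(contacts) > 0) {
      for (i in seq_len(nrow(contacts))) {
        parts <- c(parts, render_drks_address(as.list(contacts[i, ])))
      }
    }
    addresses <- paste0(
      "<ul class=\"addresses\">\n", paste(parts, collapse = ""), "</ul>\n"
    )
  }

  paste0(
    page_head(paste0(
      record$drksid, " version ", record$version_number, " (",
      record$version_date, ")"
    )),
    "<ul class=\"trial\">\n",
    drks_bullet(
      "state", paste0("Recruitment Status: ", record$recruitment_status)
    ),
    if (!is.na(record$start_date)) {
      drks_bullet(
        "schedule",
        paste0("Start Date: ", format_drks_date(record$start_date))
      )
    },
    if (!is.na(record$closing_date)) {
      drks_bullet(
        "deadline",
        paste0("Closing Date: ", format_drks_date(record$closing_date))
      )
    },
    if (!is.na(record$enrolment)) {
      drks_bullet(
        "targetSize",
        paste0(
          "Target Sample Size: ", record$enrolment,
          " Planned/Actual: ", record$enrolment_type
        )
      )
    },
    if (!is.na(record$min_age)) {
      drks_bullet("minAge", paste0("Minimum Age: ", record$min_age))
    },
    if (!is.na(record$max_age)) {
      drks_bullet("maxAge", paste0("Maximum Age: ", record$max_age))
    },
    if (!is.na(record$gender)) {
      drks_bullet("gender", paste0("Gender: ", record$gender))
    },
    "</ul>\n",
    nested_block(
      "div", "inclusionAdd", record$inclusion_criteria_additional
    ),
    nested_block("div", "exclusion", record$exclusion_criteria),
    nested_block("p", "primaryEndpoint", record$primary_outcomes),
    nested_block("p", "secondaryEndpoints", record$secondary_outcomes),
    addresses,
    "</body></html>\n"
  )
}

#' Render DRKS.de fixture pages for a ground truth
#'
#' Renders one change-history page per trial (with a "Date" column, dates in
#' the registry's `YYYY/MM/DD` dialect) and one version page per record with
#' all extraction-table elements.
#'
#' @param truth A list with a DRKS `records` history table.
#' @return List with `pages` and `index_pages`, as [render_ctgov()].
#' @export
render_drks <- function(truth) {
  records <- truth$records
  pages <- list()
  index_pages <- list()
  for (id in unique(records$drksid)) {
    rows <- records[records$drksid == id, ]
    index_pages[[id]] <- render_drks_index_page(id, rows$version_date)
    for (i in seq_len(nrow(rows))) {
      key <- paste0(id, "_", rows$version_number[i])
      pages[[key]] <- render_drks_version_page(rows[i, ])
    }
  }
  list(pages = pages, index_pages = index_pages)
}

# --- Corruption -------------------------------------------------------------

#' Corrupt a fixture page to exercise a parser failure branch
#'
#' - `"TRUNCATE"` keeps only the first 150 characters (still inside the page
#'   head), guaranteeing the version parsers' `"Error"` sentinel branch.
#' - `"DROP_TABLE"` removes the element matched by `selector`; dropping a
#'   non-essential table exercises the missing-field (`NA`) path, dropping
#'   the status table the sentinel path.
#' - `"BAD_DATE"` replaces the first date token with unparseable text,
#'   triggering the index parsers' parse error.
#'
#' @param html A rendered fixture page.
#' @param mode `"TRUNCATE"`, `"DROP_TABLE"` or `"BAD_DATE"`.
#' @param selector CSS selector for `DROP_TABLE` (default
#'   `"#EligibilityBody"`).
#' @return The corrupted HTML text.
#' @export
corrupt_page <- function(html, mode = c("TRUNCATE", "DROP_TABLE", "BAD_DATE"),
                         selector = "#EligibilityBody") {
  mode <- match.arg(mode)
  if (mode == "TRUNCATE") {
    return(substr(html, 1, 150))
  }
  if (mode == "DROP_TABLE") {
    doc <- as_html_doc(html)
    nodes <- rvest::html_elements(doc, selector)
    xml2::xml_remove(nodes)
    return(as.character(doc))
  }
  # BAD_DATE: break the first date token of either dialect
  out <- sub(
    "[A-Z][a-z]+ [0-9]{1,2}, [0-9]{4}", "Sometime 99, 9999", html
  )
  sub("[0-9]{4}/[0-9]{2}/[0-9]{2}", "9999/99/99", out)
}

#' Write fixture pages and ground truth to a directory
#'
#' Writes `<id>_index.html` and `<id>_<version>.html` for every trial in the
#' ground truth, plus `ground_truth.csv` (the history table), in the layout
#' understood by [dir_transport()].
#'
#' @param truth A ground truth from [simulate_histories()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(truth$index_pages)) {
    readr::write_file(
      truth$index_pages[[id]], file.path(dir, paste0(id, "_index.html"))
    )
  }
  for (key in names(truth$pages)) {
    readr::write_file(truth$pages[[key]], file.path(dir, paste0(key, ".html")))
  }
  write_history_csv(truth$records, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
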