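test_that("extraction rules load as the declarative selector/regex table", {
  rules <- ctgov_extraction_rules()
  get <- function(field) rules[rules$field == field, ]
  expect_identical(get("overall_status")$css, "#StudyStatusBody")
  expect_identical(get("overall_status")$regex, "Overall Status: ([A-Za-z, ]+)")
  expect_identical(get("enrolment")$css, "#StudyDesignBody")
  expect_identical(get("enrolment")$regex, "Enrollment: ([A-Za-z0-9 \\[\\]]+)")
  expect_identical(get("study_start_date")$regex, "Study Start: ([A-Za-z0-9, ]+)")
  expect_identical(
    get("primary_completion_date")$regex,
    "Primary Completion: ([A-Za-z0-9, \\[\\]]+)"
  )
  expect_identical(get("primary_completion_date_type")$regex, "(\\[[A-Za-z]+\\])")
  expect_identical(get("min_age")$regex, "Minimum Age: ([0-9]+) Years")
  expect_identical(get("max_age")$regex, "Maximum Age: ([0-9]+) Years")
  expect_identical(get("sex")$regex, "Sex: ([A-Za-z]+)")
  expect_identical(get("gender_based")$regex, "Gender Based: ([A-Za-z]+)")
  expect_identical(
    get("accepts_healthy_volunteers")$regex,
    "Accepts Healthy Volunteers: ([A-Za-z]+)"
  )
  expect_identical(get("criteria")$css, "#EligibilityBody")
  expect_identical(get("outcome_measures")$css, "#ProtocolOutcomeMeasuresBody")
  expect_identical(get("contacts")$css, "#ContactsLocationsBody")
  expect_identical(get("sponsors")$css, "#SponsorCollaboratorsBody")
  nested <- c("criteria", "outcome_measures", "contacts", "sponsors")
  expect_setequal(rules$field[rules$regex == "NESTED"], nested)
})

test_that("extract_field returns the first capture group or missing", {
  page <- wrap_page(
    "<table id='StudyStatusBody'>",
    "<tr><td>Status</td><td>Overall Status: Recruiting</td></tr>",
    "</table>"
  )
  rules <- ctgov_extraction_rules()
  status_rule <- rules[rules$field == "overall_status", ]
  expect_identical(extract_field(page, status_rule), "Recruiting")

  elig <- eligibility_table("<tr><td>Minimum Age: 18 Years</td></tr>")
  min_rule <- rules[rules$field == "min_age", ]
  expect_identical(extract_field(elig, min_rule), "18")
  # document without the eligibility table: missing, not an error
  expect_identical(extract_field(page, min_rule), NA_character_)
})

test_that("history-index dates convert to ISO-8601 in version order", {
  index <- wrap_page(
    "<table><tr><th>Version</th><th>Submitted Date</th></tr>",
    "<tr><td>1</td><td>January 5, 2010</td></tr>",
    "<tr><td>2</td><td>March 12, 2011</td></tr></table>"
  )
  expect_identical(parse_ctgov_dates(index), c("2010-01-05", "2011-03-12"))

  single <- wrap_page(
    "<table><tr><th>Submitted Date</th></tr>",
    "<tr><td>June 30, 2015</td></tr></table>"
  )
  expect_identical(parse_ctgov_dates(single), "2015-06-30")

  expect_error(parse_ctgov_dates(wrap_page("<p>no tables here</p>")),
    "Submitted Date"
  )
  bad <- wrap_page(
    "<table><tr><th>Submitted Date</th></tr>",
    "<tr><td>Sometime 99, 9999</td></tr></table>"
  )
  expect_error(parse_ctgov_dates(bad), "Sometime")
})

test_that("criteria are the lines of the cell after the Criteria: label", {
  page <- eligibility_table(paste0(
    "<tr><td>Criteria:</td>",
    "<td>Inclusion Criteria:<br/>- age over 18</td></tr>"
  ))
  expect_identical(
    decode_nested(parse_ctgov_criteria(page)),
    c("Inclusion Criteria:", "- age over 18")
  )
  expect_identical(
    parse_ctgov_criteria(eligibility_table("<tr><td>Sex: All</td></tr>")),
    NA_character_
  )
  blank <- eligibility_table("<tr><td>Criteria:</td><td></td></tr>")
  expect_identical(parse_ctgov_criteria(blank), "[]")
})

test_that("outcome rows inherit the nearest preceding section heading", {
  page <- wrap_page(
    "<table id='ProtocolOutcomeMeasuresBody'>",
    "<tr><td>Primary Outcome Measures:</td><td></td></tr>",
    "<tr><td>Measure:</td><td>OS</td></tr>",
    "<tr><td>Time Frame:</td><td>12 mo</td></tr>",
    "</table>"
  )
  out <- decode_nested(parse_ctgov_outcome_measures(page))
  expect_equal(nrow(out), 2)
  expect_identical(unique(out$section), "Primary Outcome Measures:")
  expect_identical(out$label, c("Measure:", "Time Frame:"))

  headings_only <- wrap_page(
    "<table id='ProtocolOutcomeMeasuresBody'>",
    "<tr><td>Primary Outcome Measures:</td><td></td></tr>",
    "</table>"
  )
  expect_identical(parse_ctgov_outcome_measures(headings_only), "[]")

  two_sections <- wrap_page(
    "<table id='ProtocolOutcomeMeasuresBody'>",
    "<tr><td>Primary Outcome Measures:</td><td></td></tr>",
    "<tr><td>Measure:</td><td>OS</td></tr>",
    "<tr><td>Secondary Outcome Measures:</td><td></td></tr>",
    "<tr><td>Measure:</td><td>QoL</td></tr>",
    "</table>"
  )
  out2 <- decode_nested(parse_ctgov_outcome_measures(two_sections))
  expect_identical(
    out2$section,
    c("Primary Outcome Measures:", "Secondary Outcome Measures:")
  )
})

test_that("contacts stop at the Locations: row", {
  contacts_page <- function(rows) {
    wrap_page("<table id='ContactsLocationsBody'>", rows, "</table>")
  }
  crow <- function(l, c) paste0("<tr><td>", l, "</td><td>", c, "</td></tr>")
  page <- contacts_page(paste0(
    crow("Central Contact:", "A Researcher"),
    crow("Backup Contact:", "B Trialist"),
    crow("Locations:", ""),
    crow("Location:", "Site 1"), crow("Location:", "Site 2"),
    crow("Location:", "Site 3")
  ))
  out <- decode_nested(parse_ctgov_contacts(page))
  expect_equal(nrow(out), 2)
  expect_identical(out$label, c("Central Contact:", "Backup Contact:"))

  first <- contacts_page(paste0(crow("Locations:", ""), crow("Location:", "S")))
  expect_identical(parse_ctgov_contacts(first), "[]")

  # absent boundary: all rows included, with a warning
  no_boundary <- contacts_page(crow("Central Contact:", "A Researcher"))
  expect_warning(out2 <- parse_ctgov_contacts(no_boundary), "Locations")
  expect_equal(nrow(decode_nested(out2)), 1)
})

test_that("sponsor rows are all captured in document order", {
  page <- wrap_page(
    "<table id='SponsorCollaboratorsBody'>",
    "<tr><td>Lead Sponsor:</td><td>University X</td></tr>",
    "<tr><td>Collaborator:</td><td>Institute Y</td></tr>",
    "</table>"
  )
  out <- decode_nested(parse_ctgov_sponsors(page))
  expect_identical(out$content, c("University X", "Institute Y"))
  expect_identical(
    parse_ctgov_sponsors(
      wrap_page("<table id='SponsorCollaboratorsBody'></table>")
    ),
    "[]"
  )
})

test_that("version parsing is total: well-formed pages or the Error sentinel", {
  truth <- simulate_histories(
    sim_config(n_trials = 1, registry = "ctgov", seed = 21)
  )
  rec <- truth$records[1, ]
  page <- truth$pages[[paste0(rec$nctid, "_1")]]
  parsed <- parse_ctgov_version(page, rec$nctid, 1L, rec$version_date)
  expect_equal(as.data.frame(parsed), as.data.frame(rec))
  expect_identical(sub("^[0-9]+ \\[", "[", parsed$enrolment),
    paste0("[", sub(".*\\[", "", rec$enrolment))
  )

  broken <- parse_ctgov_version(
    substr(page, 1, 150), rec$nctid, 1L, rec$version_date
  )
  expect_identical(broken$overall_status, "Error")
  expect_true(is.na(broken$min_age))
  expect_identical(broken$nctid, rec$nctid)
})

test_that("bracketed enrolment text is captured verbatim", {
  page <- wrap_page(
    "<table id='StudyStatusBody'><tr><td>Overall Status: Recruiting</td></tr></table>",
    "<table id='StudyDesignBody'>",
    "<tr><td>Enrollment: 120 [Anticipated]</td></tr></table>"
  )
  parsed <- parse_ctgov_version(page, "NCT00000001", 1L, "2020-01-01")
  expect_identical(parsed$enrolment, "120 [Anticipated]")
})

test_that("parsing inverts rendering across many randomized trials", {
  truth <- simulate_histories(
    sim_config(n_trials = 30, registry = "ctgov", seed = 87)
  )
  parsed <- dplyr::bind_rows(lapply(seq_len(nrow(truth$records)), function(i) {
    rec <- truth$records[i, ]
    key <- paste0(rec$nctid, "_", rec$version_number)
    parse_ctgov_version(
      truth$pages[[key]], rec$nctid, rec$version_number, rec$version_date
    )
  }))
  expect_equal(as.data.frame(parsed), as.data.frame(truth$records))
})
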