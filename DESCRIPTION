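Package: registryhist
Title: Clinical Trial Registry Version Histories: Download, Parse and Analyse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical trial registry entries are mutable: the responsible
    party may revise statuses, dates, enrolment targets and outcome measures
    at any time, and only the full version history reveals those changes.
    registryhist retrieves and parses complete registry entry version
    histories from two registry HTML dialects (the classic ClinicalTrials.gov
    history pages and the DRKS.de change-history pages) into long-format
    tables with one registry entry version per row, using declarative CSS
    selector plus regular expression extraction tables. Failed downloads are
    recorded as 'Error' sentinel rows so that interrupted mass downloads can
    be resumed without refetching good rows. On top of the history table the
    package implements three meta-research analyses: change in recruitment
    period length at a fixed follow-up, detection of outcome-measure changes
    via run-length comparison of canonically JSON-encoded outcome fields, and
    follow-up-corrected counts of stopped trials that avoid variable
    follow-up-time bias. A seeded synthetic registry generator renders
    ground-truth histories as registry-dialect HTML so every parser and
    analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    rlang,
    rvest,
    stringr,
    tibble,
    xml2
Suggests:
    httr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
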