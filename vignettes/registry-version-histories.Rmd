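---
title: "Registry version histories: model, extraction rules and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registry version histories: model, extraction rules and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(registryhist)
library(dplyr)
```

## Why version histories

A clinical trial registry entry is not an immutable record. The responsible
party can revise the overall status, anticipated enrolment, completion
dates and even the registered outcome measures at any time, and only the
entry's version history reveals when and how. Meta-research that reads only
the latest version of each entry is exposed to two classes of error:
silent outcome switching (the registered outcomes at publication differ
from those at launch) and variable follow-up-time bias (young trials have
had less time to be terminated than old ones, so naive event counts are
biased). registryhist downloads and parses complete version histories from
two registry HTML dialects — the classic ClinicalTrials.gov history pages
and the DRKS.de change-history pages — and implements the three analyses
that need them.

## The history table

The unit of exchange is a long-format table with **one registry entry
version per row**. Three columns identify the version — the trial id
(`nctid` or `drksid`), a 1-based `version_number` (1 = earliest) and the
ISO-8601 `version_date` — followed by the extracted data points: 16 for
ClinicalTrials.gov and 13 for DRKS.de (a date and its precision count as
two data points). `history_columns()` documents the exact serialization
order; the registry pages themselves do not prescribe one, so the order is
this package's choice and is frozen by the round-trip tests.

Scalar fields are plain text exactly as captured (ages, sex, enrolment
text such as `"120 [Anticipated]"`). Nested structures — eligibility
criteria lines, outcome-measure rows, contact rows, sponsor rows, DRKS
address bullets — are stored as **canonical JSON**: keys sorted
alphabetically, compact separators, no insignificant whitespace. Canonical
encoding makes byte equality of two cells equivalent to structural
equality of their contents, which is what the outcome-change analysis
keys on: an edit as small as one added space inside an outcome string
changes the encoding and is detected. `decode_nested()` restores the
tabular structure without loss.

Missing values serialize as empty CSV cells, deliberately distinct from
the literal text `"NA"`, which registry free text can contain. Dates carry
their precision in a sibling `*_precision` column (`"day"` or `"month"`)
rather than inside the date string, so date arithmetic downstream never
has to re-parse annotations.

## Declarative extraction

Each simple data point is one (CSS selector, regular expression) rule, and
the two rule tables (`ctgov_extraction_rules()`, `drks_extraction_rules()`)
are data, not code: the parsers iterate over them, and the tests assert
the rule strings verbatim. Matching is unanchored search; the first
matching cell in document order wins, and the first capture group (or the
whole match, for the group-less DRKS enrolment and date rules) is the
value. Element text is trimmed at the ends only — internal whitespace is
preserved so that whitespace edits remain visible downstream.

ClinicalTrials.gov dates arrive as English `"Month Day, Year"` text; dates
given only to the month are rounded to day 01 and flagged
`precision = "month"` (`"September 2009"` becomes `2009-09-01`). DRKS
dates arrive as `YYYY/MM/DD` and are always day-precise; they are
normalized to hyphenated ISO-8601.

Four table-walking rules handle nested ClinicalTrials.gov structures:
criteria are the lines of the cell after the `"Criteria:"` label;
outcome-measure rows inherit the nearest preceding section-heading row
(headings are rows whose second cell is textless, and are consumed, not
emitted); contact rows stop strictly before the `"Locations:"` row (when
that boundary row is absent, all rows are kept and a warning is raised,
since nothing marks the boundary); sponsor rows are taken whole. DRKS
nested fields are text blocks split at line breaks, and address bullets
decompose into label, affiliation, telephone, fax, email and URL, each
sub-field's own label text excluded.

## Failure as data: the Error sentinel and resume

Mass downloads fail partway. The version parsers are therefore *total*:
any input produces either a populated row or a sentinel row whose status
column is `"Error"` — never an exception that would abort a loop hours in.
A page that cannot be parsed at all, or that lacks the one structural
anchor (the status table / the recruitment-status bullet), yields the
sentinel; a page merely missing other elements yields a row with those
fields missing. `"Error"` is reserved: it collides with no legitimate
status in either vocabulary.

`download_history()` appends rows to the output CSV as they are fetched,
so an interrupted run leaves a valid partial file. `resume_download()`
re-reads the file, deletes exactly the sentinel rows, refetches those
versions (or the whole trial, when the failed row was an index placeholder
with unknown version identity) and leaves good rows untouched —
a file with no sentinel rows is not even rewritten. Iterating resume
against an eventually-recovering server converges to the same bytes a
fully successful download would have produced.

The transport — `function(url) -> html or NULL` — is injected.
`fixture_transport()`/`dir_transport()` serve rendered synthetic pages so
every test runs offline; `http_transport()` is a thin live adapter and is
best-effort only, since registries redesign their markup at will. The
fetch policy enforces a configurable minimum spacing between requests to
the same host (default 5 s — the registries publish no number, so a
conservative one is the default rather than a hard-coded constant) and a
bounded number of attempts per page.

## The three analyses

**Recruitment-length change** (`recruitment_change()`): the launch
recruitment period spans study start to primary completion as reported on
the earliest version with status `"Recruiting"` and both dates present;
the follow-up period takes the same dates from the latest version active
at the follow-up horizon (default one year after the launch start). The
change is reported as an integer percentage string
(`round(100 * fup / launch - 100)` with a `%` suffix). Trials never posted
as recruiting are excluded; trials whose only qualifying follow-up version
is missing are retained with missing follow-up fields, because dropping
them would silently shrink the denominator.

**Outcome-change detection** (`outcome_change_runs()`): versions are
scanned in order and consecutive rows with byte-identical outcome
encodings form a run; the first row of each run is emitted with its
`run_index`. Every change is reported, from outcome swaps to one-character
whitespace edits — deciding which changes are substantive is explicitly a
human-curation step, not a package feature.

**Follow-up-corrected status counts** (`followup_status()` +
`stopped_fraction()`): each trial's status is read from the version active
at a common horizon after its first version date, and trials registered
less than the follow-up period before the reference date are excluded. A
trial is stopped when that at-horizon status is `"Suspended"`,
`"Terminated"` or `"Withdrawn"`; stops after the horizon deliberately do
not count. `latest_versions()` gives the naive contrast.
`followup_bias_demo_cohort()` builds a deterministic 93-trial cohort from
published stratum counts in which the naive count finds 16 stopped trials
(17.2%) but only 10 of the 69 fully-followed trials were stopped at five
years — the remaining 6 decompose into 4 with insufficient follow-up and 2
stopped after the mark:

```{r demo}
today <- as.Date("2022-01-05")
cohort <- followup_bias_demo_cohort(today = today)
stopped_fraction(followup_status(cohort, lubridate::years(5), today = today))
```

### Numerical choices

* Calendar arithmetic uses period addition with rollback (`%m+%`): one
  year after 2016-02-29 is 2017-02-28, matching how analysts compute
  follow-up anniversaries, rather than fixed 365-day offsets.
* `stopped_fraction()` reports one decimal, rounding half **up**
  (`10/69 = 14.49...` reports `14.5`). Half-up is stated explicitly
  because base R's `round()` rounds half to even; analyses that printed
  `14.4` for this ratio truncated rather than rounded, and this package
  does not silently match that.
* Same-date version ties: "active at" queries take the later row,
  "earliest recruiting" queries the earlier row — last-wins/first-wins
  respectively, matching slice semantics on version-ordered tables.
* Percent change uses base `round()` (half to even) before the `%` suffix,
  the convention of the surrounding dplyr idiom.

## The synthetic generator

`simulate_histories()` produces trials with known ground truth and renders
them in the registry dialects, so parser and pipeline tests have an exact
oracle. Per trial it draws a version count (default 2–8), strictly
increasing version dates (first version 2010–2016, gaps of 20–300 days), a
status path from a Markov transition model over the fixture vocabulary,
and per-version edits: with `p_outcome_edit` (default 0.15) the outcome
text changes materially (a counter guarantees distinctness), otherwise
with `p_whitespace_edit` (default 0.05) a single space is inserted at an
internal position — never leading or trailing, which parsers strip and
would therefore mask. Completion dates and enrolment drift with
`p_date_edit` (default 0.2); dates are month-precise with
`p_month_precision` (default 0.3). The defaults are the package's fixed
study conditions: version counts and edit rates of this order are what
registry cohorts typically show, and the tests do not tune them.

In the fixture status model the three stopped statuses are absorbing.
Real trials occasionally resume from suspension; the absorbing choice
makes "stopped at the horizon implies stopped at latest" an invariant,
which is exactly the mechanism the follow-up-bias demonstration needs.

What the generator does **not** emulate bounds what green tests mean:
rendered pages contain the parsed element substructure, not the real
pages' chrome, encoding quirks, or historical layout drift. Passing the
round-trip suite shows the parsers invert *this dialect*; live pages can
and do diverge, which is why the transport is injectable and live use is
labelled best-effort.

`corrupt_page()` mutates rendered pages to exercise failure branches:
`TRUNCATE` (keeps 150 bytes, still inside the page head) forces the Error
sentinel, `DROP_TABLE` of a non-essential table forces the missing-field
path, and `BAD_DATE` forces the index parse error.

## Problem sizes and determinism

The test suite and the acceptance script simulate 100 trials per registry
for the end-to-end oracle (roughly 500 version pages each), 200 trials for
the follow-up parameter-recovery check, and 60 for outcome-change
recovery, all under fixed seeds; the whole suite runs in a few minutes on
one core. The generator restores the caller's RNG state, and identical
configurations render byte-identical pages.

## Known limitations

* Live scraping targets the classic ClinicalTrials.gov history dialect;
  the redesigned site and its JSON API are out of scope, as are other WHO
  network registries.
* DRKS change-history ordering on live pages is unverified; the parser
  sorts dates defensively.
* Only the documented data points are extracted; results sections,
  adverse-event tables, DRKS ethics data and study-site lists are not.
* Classifying detected outcome changes as major or minor is left to human
  raters; the package only finds and timestamps them.
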