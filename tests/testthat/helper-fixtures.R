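# Shared test helpers: quiet wrappers around the download loop, a no-delay
# fetch policy, and builders for minimal hand-written registry pages.

fast_policy <- function(retries = 1L) {
  fetch_policy(min_delay_seconds = 0, max_retries_per_page = retries)
}

quiet_download <- function(...) suppressMessages(download_history(...))
quiet_resume <- function(...) suppressMessages(resume_download(...))

truth_ids <- function(truth) {
  col <- if (truth$registry == "ctgov") "nctid" else "drksid"
  unique(truth$records[[col]])
}

# A one-table page wrapper for parser unit tests.
wrap_page <- function(...) {
  paste0("<html><head><title>t</title></head><body>", ..., "</body></html>")
}

eligibility_table <- function(rows) {
  wrap_page("<table id='EligibilityBody'>", rows, "</table>")
}

# Build a ctgov history row with the given fields, all others missing.
ctgov_row <- function(...) {
  registryhist:::ctgov_record(...)
}

drks_row <- function(...) {
  registryhist:::drks_record(...)
}

# Stopped status vocabulary used throughout the analyses.
STOPPED <- c("Suspended", "Terminated", "Withdrawn")

naive_stopped <- function(history) {
  out <- latest_versions(history)
  out$stopped <- out$overall_status %in% STOPPED
  out
}
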