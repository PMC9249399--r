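# Synthetic registry histories with known ground truth, rendered as
# registry-dialect HTML.
#
# The generator simulates trial registration histories (status transitions,
# enrolment and completion-date drift, outcome-measure edits down to
# single-whitespace changes) and renders each version as a page in the
# corresponding registry dialect, so that the full
# render -> transport -> download -> CSV pipeline can be exercised offline
# against exact ground truth. The templates emulate the parsed-element
# substructure of the registry pages, not their visual chrome; they are the
# contract the parsers are tested against.

# Fixture status vocabulary (not a registry-complete list): the stopped
# subset plus common active states.
CTGOV_STATUSES <- c(
  "Recruiting", "Active not recruiting", "Completed",
  "Terminated", "Suspended", "Withdrawn"
)

DRKS_STATUSES <- c(
  "Recruiting planned", "Recruiting ongoing",
  "Recruiting complete, study ongoing", "Recruiting complete, study complete",
  "Recruiting stopped after recruiting started",
  "Recruiting suspended on temporary hold"
)

# Default per-version status transition matrices (rows sum to 1).
ctgov_status_model <- function() {
  states <- CTGOV_STATUSES
  transition <- rbind(
    Recruiting = c(0.70, 0.12, 0.08, 0.05, 0.03, 0.02),
    `Active not recruiting` = c(0.00, 0.65, 0.25, 0.07, 0.03, 0.00),
    Completed = c(0, 0, 1, 0, 0, 0),
    # stopped statuses are absorbing in the fixture model: a stopped trial
    # stays stopped, so a status stopped at the horizon is also stopped on
    # the latest version
    Terminated = c(0, 0, 0, 1, 0, 0),
    Suspended = c(0, 0, 0, 0, 1, 0),
    Withdrawn = c(0, 0, 0, 0, 0, 1)
  )
  colnames(transition) <- states
  list(
    states = states,
    initial = stats::setNames(c(0.85, 0.05, 0, 0, 0, 0.10), states),
    transition = transition
  )
}

drks_status_model <- function() {
  states <- DRKS_STATUSES
  transition <- rbind(
    c(0.30, 0.55, 0.00, 0.00, 0.10, 0.05),
    c(0.00, 0.60, 0.20, 0.08, 0.07, 0.05),
    c(0.00, 0.00, 0.70, 0.28, 0.02, 0.00),
    c(0, 0, 0, 1, 0, 0),
    c(0, 0, 0, 0, 1, 0),
    c(0.00, 0.30, 0.00, 0.00, 0.30, 0.40)
  )
  dimnames(transition) <- list(states, states)
  list(
    states = states,
    initial = stats::setNames(c(0.30, 0.60, 0.05, 0, 0.02, 0.03), states),
    transition = transition
  )
}

#' Configuration for the synthetic registry generator
#'
#' @param n_trials Number of trials to simulate.
#' @param registry `"ctgov"` or `"drks"`.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   rendered pages.
#' @param version_count_range Integer pair, inclusive range of versions per
#'   trial.
#' @param status_model List with `states`, `initial` probabilities and a
#'   `transition` matrix; defaults to the registry's built-in model.
#' @param p_outcome_edit Per-version probability of a material outcome-text
#'   edit (guaranteed distinct from all earlier texts).
#' @param p_whitespace_edit Per-version probability of inserting one space
#'   inside an outcome string (never leading/trailing, which parsers strip).
#' @param p_date_edit Per-version probability of drifting the completion
#'   date, and independently the enrolment figure.
#' @param p_month_precision Probability that a trial reports a date only to
#'   the month (ClinicalTrials.gov only; DRKS dates are always day-precise).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trials = 10,
                       registry = c("ctgov", "drks"),
                       seed = 1L,
                       version_count_range = c(2L, 8L),
                       status_model = NULL,
                       p_outcome_edit = 0.15,
                       p_whitespace_edit = 0.05,
                       p_date_edit = 0.2,
                       p_month_precision = 0.3) {
  registry <- match.arg(registry)
  probs <- c(p_outcome_edit, p_whitespace_edit, p_date_edit, p_month_precision)
  if (any(probs < 0 | probs > 1)) {
    stop("all edit probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(version_count_range) != 2 || version_count_range[1] < 1 ||
    version_count_range[2] < version_count_range[1]) {
    stop("version_count_range must be an increasing pair with lower bound >= 1",
      call. = FALSE
    )
  }
  if (is.null(status_model)) {
    status_model <- if (registry == "ctgov") {
      ctgov_status_model()
    } else {
      drks_status_model()
    }
  }
  structure(
    list(
      n_trials = as.integer(n_trials),
      registry = registry,
      seed = as.integer(seed),
      version_count_range = as.integer(version_count_range),
      status_model = status_model,
      p_outcome_edit = p_outcome_edit,
      p_whitespace_edit = p_whitespace_edit,
      p_date_edit = p_date_edit,
      p_month_precision = p_month_precision
    ),
    class = "sim_config"
  )
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

markov_path <- function(model, n) {
  path <- character(n)
  path[1] <- sample(model$states, 1, prob = model$initial)
  for (i in seq_len(n - 1)) {
    path[i + 1] <- sample(
      model$states, 1,
      prob = model$transition[path[i], ]
    )
  }
  path
}

# Insert one space at a random internal position of a string; the result is
# always one character longer, hence always differs from the input.
insert_internal_space <- function(text) {
  n <- nchar(text)
  if (n < 2) return(paste0(text, " .")) # degenerate, keeps the guarantee
  pos <- sample(seq_len(n - 1), 1)
  paste0(substr(text, 1, pos), " ", substr(text, pos + 1, n))
}

floor_month <- function(date) {
  as.Date(format(date, "%Y-%m-01"))
}

CONDITIONS <- c(
  "glioblastoma", "type 2 diabetes", "major depressive disorder",
  "chronic heart failure", "rheumatoid arthritis", "advanced melanoma"
)

OUTCOME_TEXTS <- c(
  "Overall survival at 12 months",
  "Change in HbA1c at 26 weeks",
  "Progression-free survival at 24 months",
  "Change in MADRS total score at 8 weeks",
  "Six minute walk distance at 12 weeks"
)

SPONSOR_ORGS <- c(
  "University Hospital A", "National Cancer Consortium",
  "Midlands Clinical Research Centre", "Institute of Metabolic Medicine"
)

PEOPLE <- c(
  "A Researcher, MD", "B Trialist, PhD", "C Investigator, MD PhD",
  "D Coordinator, MSc"
)

# --- ClinicalTrials.gov simulation ------------------------------------------

simulate_ctgov_trial <- function(id, config) {
  lo <- config$version_count_range[1]
  hi <- config$version_count_range[2]
  n_versions <- lo + sample.int(hi - lo + 1L, 1) - 1L
  first_date <- as.Date("2010-01-01") + sample(0:2191, 1)
  gaps <- if (n_versions > 1) sample(20:300, n_versions - 1, replace = TRUE)
  version_dates <- first_date + cumsum(c(0, gaps))[seq_len(n_versions)]
  statuses <- markov_path(config$status_model, n_versions)

  start_precision <- if (stats::runif(1) < config$p_month_precision) {
    "month"
  } else {
    "day"
  }
  pcd_precision <- if (stats::runif(1) < config$p_month_precision) {
    "month"
  } else {
    "day"
  }
  start_date <- first_date + sample(-30:90, 1)
  if (start_precision == "month") start_date <- floor_month(start_date)
  pcd <- start_date + sample(180:1095, 1)
  if (pcd_precision == "month") pcd <- floor_month(pcd)
  enrolment_n <- sample(20:500, 1)
  v1_missing_pcd <- stats::runif(1) < 0.15

  condition <- sample(CONDITIONS, 1)
  primary_text <- sample(OUTCOME_TEXTS, 1)
  secondary_text <- sample(setdiff(OUTCOME_TEXTS, primary_text), 1)
  min_age <- as.character(sample(18:40, 1))
  max_age <- as.character(sample(60:85, 1))
  sex <- sample(c("All", "Female", "Male"), 1, prob = c(0.8, 0.1, 0.1))
  healthy <- sample(c("No", "Yes"), 1, prob = c(0.7, 0.3))
  criteria_lines <- c(
    "Inclusion Criteria:",
    paste0("- diagnosis of ", condition),
    paste0("- age over ", min_age),
    "Exclusion Criteria:",
    "- prior enrolment in a conflicting study"
  )
  contacts <- list(
    list(label = "Central Contact:", content = sample(PEOPLE, 1))
  )
  sponsors <- list(
    list(label = "Lead Sponsor:", content = sample(SPONSOR_ORGS, 1))
  )
  if (stats::runif(1) < 0.4) {
    sponsors[[2]] <- list(
      label = "Collaborator:", content = sample(SPONSOR_ORGS, 1)
    )
  }

  edit_counter <- 0L
  rows <- vector("list", n_versions)
  changed <- logical(n_versions)
  for (v in seq_len(n_versions)) {
    if (v > 1) {
      if (stats::runif(1) < config$p_outcome_edit) {
        edit_counter <- edit_counter + 1L
        primary_text <- paste0(
          sample(OUTCOME_TEXTS, 1), " (amended ", edit_counter, ")"
        )
        changed[v] <- TRUE
      } else if (stats::runif(1) < config$p_whitespace_edit) {
        primary_text <- insert_internal_space(primary_text)
        changed[v] <- TRUE
      }
      if (stats::runif(1) < config$p_date_edit) {
        pcd <- pcd + sample(30:360, 1)
        if (pcd_precision == "month") pcd <- floor_month(pcd)
      }
      if (stats::runif(1) < config$p_date_edit) {
        enrolment_n <- max(10, enrolment_n + sample(-50:100, 1))
      }
    }
    pcd_missing <- v == 1 && v1_missing_pcd
    pcd_type <- if (statuses[v] == "Completed") "Actual" else "Anticipated"
    outcome_rows <- list(
      list(
        section = "Primary Outcome Measures:", label = "Measure:",
        content = primary_text
      ),
      list(
        section = "Primary Outcome Measures:", label = "Time Frame:",
        content = "12 months"
      ),
      list(
        section = "Secondary Outcome Measures:", label = "Measure:",
        content = secondary_text
      )
    )
    rows[[v]] <- ctgov_record(
      nctid = id,
      version_number = v,
      version_date = as.character(version_dates[v]),
      overall_status = statuses[v],
      enrolment = paste0(
        enrolment_n, " [",
        if (statuses[v] == "Completed") "Actual" else "Anticipated", "]"
      ),
      study_start_date = as.character(start_date),
      start_date_precision = start_precision,
      primary_completion_date = if (pcd_missing) {
        NA_character_
      } else {
        as.character(pcd)
      },
      primary_completion_date_precision = if (pcd_missing) {
        NA_character_
      } else {
        pcd_precision
      },
      primary_completion_date_type = if (pcd_missing) {
        NA_character_
      } else {
        pcd_type
      },
      min_age = min_age,
      max_age = max_age,
      sex = sex,
      gender_based = "No",
      accepts_healthy_volunteers = healthy,
      criteria = encode_nested(criteria_lines),
      outcome_measures = encode_nested(outcome_rows),
      contacts = encode_nested(contacts),
      sponsors = encode_nested(sponsors)
    )
  }
  list(records = dplyr::bind_rows(rows), outcome_changed = changed)
}

# --- DRKS simulation --------------------------------------------------------

simulate_drks_trial <- function(id, config) {
  lo <- config$version_count_range[1]
  hi <- config$version_count_range[2]
  n_versions <- lo + sample.int(hi - lo + 1L, 1) - 1L
  first_date <- as.Date("2010-01-01") + sample(0:2191, 1)
  gaps <- if (n_versions > 1) sample(20:300, n_versions - 1, replace = TRUE)
  version_dates <- first_date + cumsum(c(0, gaps))[seq_len(n_versions)]
  statuses <- markov_path(config$status_model, n_versions)

  start_date <- first_date + sample(-30:90, 1)
  closing <- start_date + sample(180:1095, 1)
  enrolment_n <- sample(20:500, 1)
  v1_missing_closing <- stats::runif(1) < 0.15

  primary_text <- sample(OUTCOME_TEXTS, 1)
  secondary_text <- sample(setdiff(OUTCOME_TEXTS, primary_text), 1)
  min_age <- paste(sample(18:40, 1), "Years")
  max_age <- sample(
    c(paste(sample(60:85, 1), "Years"), "no maximum age"),
    1,
    prob = c(0.8, 0.2)
  )
  gender <- sample(c("Both", "Female", "Male"), 1, prob = c(0.8, 0.1, 0.1))
  inclusion_add <- c(
    paste0("- diagnosis of ", sample(CONDITIONS, 1)),
    "- written informed consent"
  )
  exclusion <- c("- pregnancy or breastfeeding", "- severe renal impairment")
  contact <- list(
    label = sample(c("Primary Sponsor", "Scientific Contact"), 1),
    affiliation = sample(SPONSOR_ORGS, 1),
    telephone = if (stats::runif(1) < 0.7) {
      paste0("+49 30 ", sample(1000000:9999999, 1))
    } else {
      NA_character_
    },
    fax = if (stats::runif(1) < 0.5) {
      paste0("+49 30 ", sample(1000000:9999999, 1))
    } else {
      NA_character_
    },
    email = if (stats::runif(1) < 0.8) {
      "study-office@example.org"
    } else {
      NA_character_
    },
    url = if (stats::runif(1) < 0.5) {
      "https://trials.example.org"
    } else {
      NA_character_
    }
  )

  edit_counter <- 0L
  rows <- vector("list", n_versions)
  changed <- logical(n_versions)
  for (v in seq_len(n_versions)) {
    if (v > 1) {
      if (stats::runif(1) < config$p_outcome_edit) {
        edit_counter <- edit_counter + 1L
        primary_text <- paste0(
          sample(OUTCOME_TEXTS, 1), " (amended ", edit_counter, ")"
        )
        changed[v] <- TRUE
      } else if (stats::runif(1) < config$p_whitespace_edit) {
        primary_text <- insert_internal_space(primary_text)
        changed[v] <- TRUE
      }
      if (stats::runif(1) < config$p_date_edit) {
        closing <- closing + sample(30:360, 1)
      }
      if (stats::runif(1) < config$p_date_edit) {
        enrolment_n <- max(10, enrolment_n + sample(-50:100, 1))
      }
    }
    closing_missing <- v == 1 && v1_missing_closing
    rows[[v]] <- drks_record(
      drksid = id,
      version_number = v,
      version_date = as.character(version_dates[v]),
      recruitment_status = statuses[v],
      start_date = as.character(start_date),
      closing_date = if (closing_missing) {
        NA_character_
      } else {
        as.character(closing)
      },
      enrolment = as.integer(enrolment_n),
      enrolment_type = if (grepl("complete", statuses[v])) {
        "Actual"
      } else {
        "Planned"
      },
      min_age = min_age,
      max_age = max_age,
      gender = gender,
      inclusion_criteria_additional = encode_nested(inclusion_add),
      exclusion_criteria = encode_nested(exclusion),
      primary_outcomes = encode_nested(primary_text),
      secondary_outcomes = encode_nested(secondary_text),
      contacts = encode_nested(list(contact))
    )
  }
  list(records = dplyr::bind_rows(rows), outcome_changed = changed)
}

#' Deterministic cohort demonstrating variable-follow-up-time bias
#'
#' Builds a ClinicalTrials.gov-schema history table for a cohort whose
#' composition is given by counts, reproducing the classic bias mechanism:
#' counting stopped trials from latest statuses inflates (or deflates) the
#' rate relative to assessing every trial at a common follow-up horizon.
#' Five strata are generated: long-followed never-stopped trials; trials
#' stopped before the horizon; trials stopped only after the horizon; young
#' stopped trials (insufficient follow-up, excluded by the correction); and
#' young active trials. With the defaults, 16 of 93 trials are stopped on
#' their latest version but only 10 of the 69 trials with full follow-up
#' were stopped at the five-year horizon.
#'
#' @param n_total Cohort size.
#' @param n_stopped_early Trials stopped before the follow-up horizon.
#' @param n_stopped_late Trials with full follow-up whose stop postdates the
#'   horizon.
#' @param n_young_stopped Stopped trials registered less than the follow-up
#'   period before `today`.
#' @param n_young_active Active trials registered less than the follow-up
#'   period before `today`.
#' @param today Reference date of the analysis.
#' @return ClinicalTrials.gov history table.
#' @export
#' @examples
#' cohort <- followup_bias_demo_cohort()
#' stopped_fraction(followup_status(cohort, today = as.Date("2022-01-05")))
followup_bias_demo_cohort <- function(n_total = 93,
                                      n_stopped_early = 10,
                                      n_stopped_late = 2,
                                      n_young_stopped = 4,
                                      n_young_active = 20,
                                      today = as.Date("2022-01-05")) {
  n_old_active <- n_total - n_stopped_early - n_stopped_late -
    n_young_stopped - n_young_active
  if (n_old_active < 0) {
    stop("stratum counts exceed n_total", call. = FALSE)
  }
  today <- as.Date(today)
  old_start <- today %m-% lubridate::years(7)
  young_start <- today %m-% lubridate::years(3)
  stopped_statuses <- c("Terminated", "Suspended", "Withdrawn")

  rows <- list()
  serial <- 0L
  add_trial <- function(first_date, stop_date = NULL, stop_status = NULL) {
    serial <<- serial + 1L
    id <- sprintf("NCT%08d", 90000000 + serial)
    rows[[length(rows) + 1]] <<- ctgov_record(
      nctid = id, version_number = 1L,
      version_date = as.character(first_date),
      overall_status = "Recruiting"
    )
    if (!is.null(stop_date)) {
      rows[[length(rows) + 1]] <<- ctgov_record(
        nctid = id, version_number = 2L,
        version_date = as.character(stop_date),
        overall_status = stop_status
      )
    }
  }

  for (i in seq_len(n_old_active)) add_trial(old_start)
  for (i in seq_len(n_stopped_early)) {
    add_trial(
      old_start, old_start %m+% lubridate::years(2),
      stopped_statuses[(i - 1) %% 3 + 1]
    )
  }
  for (i in seq_len(n_stopped_late)) {
    add_trial(
      old_start, old_start %m+% lubridate::years(6),
      stopped_statuses[(i - 1) %% 3 + 1]
    )
  }
  for (i in seq_len(n_young_stopped)) {
    add_trial(
      young_start, young_start %m+% lubridate::years(2),
      stopped_statuses[(i - 1) %% 3 + 1]
    )
  }
  for (i in seq_len(n_young_active)) add_trial(young_start)
  dplyr::bind_rows(rows)
}

#' Simulate registry histories with known ground truth
#'
#' Generates `n_trials` trial registration histories under the configured
#' status-transition model and edit probabilities, then renders every
#' version as a page in the registry's HTML dialect. Deterministic given the
#' seed: identical configurations give byte-identical pages.
#'
#' @param config A [sim_config()].
#' @return A `ground_truth` list with elements `registry`, `records` (the
#'   history table the parsers must recover, one version per row),
#'   `outcome_edits` (tibble of planted outcome-change flags per version),
#'   `pages` (named list, `"<id>_<version>"` -> HTML) and `index_pages`
#'   (named list, `"<id>"` -> history-index HTML).
#' @export
simulate_histories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_rng(config$seed, {
    prefix <- if (config$registry == "ctgov") "NCT" else "DRKS"
    ids <- sprintf("%s%08d", prefix, 10000000 + seq_len(config$n_trials))
    sims <- lapply(ids, function(id) {
      if (config$registry == "ctgov") {
        simulate_ctgov_trial(id, config)
      } else {
        simulate_drks_trial(id, config)
      }
    })
    records <- dplyr::bind_rows(lapply(sims, function(s) s$records))
    outcome_edits <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
      tibble::tibble(
        trial = ids[i],
        version_number = seq_along(sims[[i]]$outcome_changed),
        outcome_changed = sims[[i]]$outcome_changed
      )
    }))
    truth <- list(
      registry = config$registry,
      records = records,
      outcome_edits = outcome_edits
    )
    pages <- if (config$registry == "ctgov") {
      render_ctgov(truth)
    } else {
      render_drks(truth)
    }
    truth$pages <- pages$pages
    truth$index_pages <- pages$index_pages
    class(truth) <- "ground_truth"
    truth
  })
}
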