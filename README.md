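# registryhist

Clinical trial registry entries look like fixed records but are mutable:
the responsible party can change the overall status, enrolment target,
completion dates and even the registered outcome measures at any time.
Meta-researchers, systematic reviewers and peer reviewers who read only
the *latest* version of an entry risk missing outcome switching and
mis-counting events under variable follow-up time. registryhist is an R
package that downloads and parses **complete registry entry version
histories** — from the classic ClinicalTrials.gov history pages and the
DRKS.de change-history pages — into long-format tables (one registry
entry version per row), and implements the three analyses that need them:

1. **Recruitment-length change** — percentage change of the recruitment
   period between the version posted at launch (first version with status
   "Recruiting") and the version active a fixed follow-up later:
   `round(100 · len_fup / len_launch − 100)` rendered as e.g. `"50%"`.
2. **Outcome-change detection** — runs of consecutive versions with
   byte-identical outcome measures (canonically JSON-encoded, so byte
   equality ⇔ structural equality); every run boundary is a detected
   change, down to a single whitespace character. Deciding which changes
   matter is left to human curation.
3. **Follow-up-corrected status counts** — every trial's status assessed
   at a common horizon after first registration (trials with insufficient
   follow-up excluded), so that "stopped" fractions
   (Terminated/Suspended/Withdrawn) are not biased by young trials.

Extraction is declarative: each data point is a (CSS selector, regex)
rule — 16 data points per ClinicalTrials.gov version, 13 per DRKS
version. Download failures become `"Error"` sentinel rows rather than
exceptions, and `resume_download()` refetches exactly those rows, so
mass downloads are interruption-safe. A seeded synthetic registry
generator (`simulate_histories()`) renders ground-truth histories as
registry-dialect HTML, making the entire pipeline testable offline.

## Worked example (offline, synthetic registry)

```r
library(registryhist)
library(dplyr)

# Simulate 3 trials with rendered ClinicalTrials.gov-dialect pages,
# then download their histories through the fixture transport.
truth <- simulate_histories(sim_config(n_trials = 3, registry = "ctgov",
                                       seed = 2024))
hv <- download_history(
  unique(truth$records$nctid),
  policy    = fetch_policy(min_delay_seconds = 0),
  transport = fixture_transport(truth)
)
dim(hv)
#> [1] 14 19     # 14 registry entry versions, 3 id columns + 16 data points

hv[1:2, c("nctid", "version_number", "version_date", "overall_status")]
#>   nctid       version_number version_date overall_status
#> 1 NCT10000001              1 2011-07-03   Recruiting
#> 2 NCT10000001              2 2011-09-05   Active not recruiting

recruitment_change(hv, lubridate::years(1))
#>   nctid       recruitment_length_at_launch recruitment_length_at_fup recruitment_length_change
#> 1 NCT10000001                          208                       541 160%
#> 2 NCT10000002                          822                      1059 29%
#> 3 NCT10000003                         1052                      1052 0%
```

The first trial's anticipated recruitment period grew from 208 to 541
days within a year of launch (+160%); the third trial's dates never
moved (0%). `outcome_change_runs(hv)` lists each trial's outcome-measure
versions the same way (here 7 runs across 14 versions), and
`followup_status()` + `stopped_fraction()` give horizon-corrected
stopped-trial fractions. For live use, replace the transport with
`http_transport()` (best-effort: registry sites change their markup) or
drop the `transport` argument.

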