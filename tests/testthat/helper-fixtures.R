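# Shared fixture builders. Elapsed-time conventions are re-derived here
# (days / 30.44 per month, / 365.25 per year) so expected values are
# computed independently of the package's internals.

MO <- 30.44
YR <- 365.25

# PSA series following an exact exponential P0 * 2^(t/D), with t the
# elapsed months implied by the actual (day-rounded) calendar dates.
exp_series <- function(p0, psadt_months, months, id = "P1",
                       origin = as.Date("2010-01-01")) {
  dates <- origin + round(months * MO)
  t_mo <- as.numeric(dates - origin) / MO
  psa_series(id, dates, p0 * 2^(t_mo / psadt_months))
}

# Independent OLS slope/intercept via the textbook sum formulas.
ols_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

write_cohort_csvs <- function(dir, psa_lines, staging_lines = NULL,
                              treatment_lines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("patient_id,date,psa_ng_ml", psa_lines),
             file.path(dir, "psa.csv"))
  writeLines(c(paste0("patient_id,tnm,gleason,prostate_volume_ml,",
                      "life_expectancy_years"), staging_lines),
             file.path(dir, "staging.csv"))
  writeLines(c("patient_id,modality,date,pre_treatment_psa_ng_ml",
               treatment_lines),
             file.path(dir, "treatments.csv"))
  dir
}

# A single-patient record with one treatment and chosen post-treatment
# PSA values at given follow-up months.
audit_record <- function(id, modality, pre_psa, months, post_psa,
                         treat_date = as.Date("2011-06-01")) {
  dates <- treat_date + round(months * MO)
  series <- psa_series(id, c(treat_date - 60, dates), c(pre_psa, post_psa))
  patient_record(id, series,
                 treatments = list(treatment_event(modality, treat_date,
                                                   pre_psa)))
}

guideline_yaml <- function(text) {
  f <- tempfile(fileext = ".yaml")
  writeLines(text, f)
  f
}

# Toy branch graph: entry -> therapyA (psa > 20) / therapyB (psa <= 20)
toy_branch_graph <- function() {
  load_guideline(guideline_yaml("
entry: entry
facts:
  psa: numeric
nodes:
  - {id: entry, label: Entry, kind: decision, predicate: true}
  - {id: therapyA, label: A, kind: therapy, predicate: 'psa > 20'}
  - {id: therapyB, label: B, kind: therapy, predicate: 'psa <= 20'}
edges:
  - {from: entry, to: therapyA}
  - {from: entry, to: therapyB}
"))
}

# Gleason object with a given sum (sum 2 is only reachable as patterns 1+1).
new_gleason_for_test <- function(gs) {
  parse_gleason(if (gs == 2) "1+1" else as.character(gs))
}
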