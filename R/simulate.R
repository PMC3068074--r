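#' Synthetic PSA cohort simulation
#'
#' Generates longitudinal patient records with known ground truth so the
#' kinetics estimators, the risk stratifier, the guideline engine and the
#' outcome audit can all be exercised — and checked against the
#' simulator's own bookkeeping — without clinical data.
#'
#' The generative model, per patient:
#'
#' 1. **Pre-treatment growth.** PSA follows `P(t) = P0 * 2^(t / D)` with
#'    baseline `P0` and doubling time `D` drawn uniformly from the
#'    configured ranges; measurements are taken at a quarterly schedule
#'    spanning three years by default — long enough that doubling times at
#'    the slow end of the range leave an estimable trend.
#' 2. **Treatment.** Surgery or radiotherapy (Bernoulli with the
#'    configured surgery proportion) 21 days after the last pre-treatment
#'    visit, dropping PSA to a modality-specific nadir.
#' 3. **Recurrence.** With the configured probability, exponential regrowth
#'    from the nadir at the patient's own doubling time resumes after a
#'    delay drawn uniformly from 3–9 months post-treatment.
#' 4. **Observation.** Every measurement is perturbed by multiplicative
#'    log-normal noise (`sdlog = noise_cv`; `noise_cv = 0` gives exact
#'    values); post-treatment visits follow the follow-up schedule and are
#'    independently missed with the dropout probability.
#'
#' Staging, Gleason patterns, prostate volume and life expectancy are drawn
#' from fixed distributions spanning the stratifier's domain (T1c–T2c,
#' patterns 2–5). Identical seeds give byte-identical outputs; each patient
#' has an independent seed derived from the cohort seed, so cohorts are
#' reproducible patient-by-patient.
#'
#' @name synthetic_cohort
NULL

#' Simulation parameters
#'
#' Defaults emulate a small single-centre pilot cohort: 95 patients of
#' whom roughly 61 undergo surgery and 34 radiotherapy, followed up to 12
#' months on a 1/3/6/9/12-month schedule.
#'
#' @param n_patients Number of patients (>= 0).
#' @param baseline_psa_range Uniform range for baseline PSA, ng/mL.
#' @param true_psadt_range Uniform range for the true doubling time,
#'   months.
#' @param pretreat_schedule Pre-treatment measurement months (attended in
#'   full; dropout applies to follow-up visits only).
#' @param treatment_mix Probability a patient is treated surgically (the
#'   remainder receive radiotherapy); default 61/95.
#' @param post_surgery_nadir,post_radio_nadir Post-treatment PSA nadir,
#'   ng/mL.
#' @param recurrence_prob Probability of biochemical recurrence.
#' @param noise_cv `sdlog` of the multiplicative log-normal measurement
#'   noise (0 = noiseless).
#' @param visit_schedule Post-treatment follow-up months.
#' @param dropout_prob_per_visit Probability each follow-up visit is
#'   missed.
#' @param seed Integer seed; drives every random draw.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_patients = 95,
                       baseline_psa_range = c(2, 20),
                       true_psadt_range = c(12, 48),
                       pretreat_schedule = seq(0, 36, by = 3),
                       treatment_mix = 61 / 95,
                       post_surgery_nadir = 0.05,
                       post_radio_nadir = 1.0,
                       recurrence_prob = 0.2,
                       noise_cv = 0.1,
                       visit_schedule = c(1, 3, 6, 9, 12),
                       dropout_prob_per_visit = 0.1,
                       seed = 1L) {
  stopifnot(n_patients >= 0,
            length(baseline_psa_range) == 2, all(baseline_psa_range > 0),
            length(true_psadt_range) == 2, all(true_psadt_range > 0),
            treatment_mix >= 0, treatment_mix <= 1,
            post_surgery_nadir > 0, post_radio_nadir > 0,
            length(pretreat_schedule) >= 2,
            recurrence_prob >= 0, recurrence_prob <= 1,
            noise_cv >= 0, length(visit_schedule) >= 1,
            dropout_prob_per_visit >= 0, dropout_prob_per_visit <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 baseline_psa_range = baseline_psa_range,
                 true_psadt_range = true_psadt_range,
                 pretreat_schedule = pretreat_schedule,
                 treatment_mix = treatment_mix,
                 post_surgery_nadir = post_surgery_nadir,
                 post_radio_nadir = post_radio_nadir,
                 recurrence_prob = recurrence_prob,
                 noise_cv = noise_cv,
                 visit_schedule = visit_schedule,
                 dropout_prob_per_visit = dropout_prob_per_visit,
                 seed = as.integer(seed)),
            class = "sim_params")
}

SIM_BASELINE_DATE <- as.Date("2009-01-01")
TREATMENT_LAG_DAYS <- 21      # > 45-day audit window behind the month-1 visit
RECURRENCE_DELAY_MONTHS <- c(3, 9)

#' Simulate one patient trajectory
#'
#' @param params A [sim_params()].
#' @param patient_index 1-based patient index; together with `params$seed`
#'   it determines the patient's private random stream.
#' @return A list with the emitted `record` ([patient_record()]) and
#'   `truth`: a data frame of the simulator's bookkeeping — the true
#'   doubling time (months), modality, recurrence flag, and the
#'   threshold-criterion outcome at each follow-up month that had a visit.
#' @export
simulate_trajectory <- function(params, patient_index) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((params$seed + 7919L * patient_index) %% 2147483647L)

  id <- sprintf("P%04d", patient_index)
  p0 <- stats::runif(1, params$baseline_psa_range[1],
                     params$baseline_psa_range[2])
  psadt <- stats::runif(1, params$true_psadt_range[1],
                        params$true_psadt_range[2])
  modality <- if (stats::runif(1) < params$treatment_mix) "surgery"
              else "radiotherapy"
  nadir <- if (modality == "surgery") params$post_surgery_nadir
           else params$post_radio_nadir
  recurred <- stats::runif(1) < params$recurrence_prob
  rec_delay_mo <- stats::runif(1, RECURRENCE_DELAY_MONTHS[1],
                               RECURRENCE_DELAY_MONTHS[2])

  observe <- function(true_psa) {
    true_psa * exp(stats::rnorm(length(true_psa), 0, params$noise_cv))
  }

  # pre-treatment visits: exponential growth sampled quarterly
  pre_dates <- SIM_BASELINE_DATE +
    round(unit_to_days(params$pretreat_schedule, "months"))
  pre_months <- as.numeric(pre_dates - SIM_BASELINE_DATE) / DAYS_PER_MONTH
  pre_true <- p0 * 2^(pre_months / psadt)
  pre_obs <- observe(pre_true)

  treat_date <- pre_dates[length(pre_dates)] + TREATMENT_LAG_DAYS
  event <- treatment_event(modality, treat_date,
                           pre_treatment_psa = pre_obs[length(pre_obs)])

  # post-treatment visits: nadir, then regrowth if recurred
  post_months <- params$visit_schedule
  attended <- stats::runif(length(post_months)) >=
    params$dropout_prob_per_visit
  post_dates <- treat_date + round(unit_to_days(post_months, "months"))
  post_elapsed_mo <- as.numeric(post_dates - treat_date) / DAYS_PER_MONTH
  post_true <- ifelse(recurred & post_elapsed_mo > rec_delay_mo,
                      nadir * 2^((post_elapsed_mo - rec_delay_mo) / psadt),
                      nadir)
  post_obs <- observe(post_true)

  series <- psa_series(id,
                       c(pre_dates, post_dates[attended]),
                       c(pre_obs, post_obs[attended]))

  t_cat <- sample(c("T1c", "T2a", "T2b", "T2c"), 1,
                  prob = c(0.35, 0.25, 0.25, 0.15))
  g1 <- sample(2:5, 1)
  g2 <- sample(2:5, 1)
  gleason <- new_gleason(g1, g2, g1 + g2)
  stage <- structure(list(t_category = t_cat, n_category = "N0",
                          m_category = "M0"), class = "clinical_stage")
  record <- patient_record(
    id, series, stage = stage, gleason = gleason,
    prostate_volume = round(stats::runif(1, 20, 60), 1),
    treatments = list(event),
    life_expectancy = round(stats::runif(1, 5, 25)))

  threshold <- if (modality == "surgery") 0.2 else 2.0
  truth <- data.frame(
    patient_id = id,
    true_psadt_months = psadt,
    modality = modality,
    recurred = recurred,
    month = post_months[attended],
    outcome = ifelse(post_obs[attended] < threshold, "success", "failure"))
  list(record = record, truth = truth)
}

#' Simulate a cohort
#'
#' Runs [simulate_trajectory()] for each patient and optionally writes the
#' records in the [read_cohort()] formats plus a `truth.csv` ground-truth
#' sidecar (so tests compare against a file, never against private
#' simulator state). Identical parameters (including seed) yield
#' byte-identical files.
#'
#' @param params A [sim_params()].
#' @param out_dir Optional output directory.
#' @return Invisibly, a list: `cohort` (a `psa_cohort`), `truth` (data
#'   frame), and `paths` (written files, when `out_dir` is given).
#' @export
simulate_cohort <- function(params = sim_params(), out_dir = NULL) {
  sims <- lapply(seq_len(params$n_patients),
                 function(i) simulate_trajectory(params, i))
  cohort <- structure(lapply(sims, `[[`, "record"), class = "psa_cohort")
  truth <- do.call(rbind, c(list(data.frame(
    patient_id = character(), true_psadt_months = numeric(),
    modality = character(), recurred = logical(), month = numeric(),
    outcome = character())),
    lapply(sims, `[[`, "truth")))
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_cohort(cohort, out_dir)
    truth_path <- file.path(out_dir, "truth.csv")
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, truth_path)
  }
  invisible(list(cohort = cohort, truth = truth, paths = paths))
}
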