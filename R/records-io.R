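#' Clinical record types and delimited-file input/output
#'
#' Patient records combine an ordered PSA measurement series with clinical
#' staging (TNM), Gleason grading, optional prostate volume and life
#' expectancy, and a treatment history. Records are exchanged as three
#' comma-delimited files sharing a `patient_id` key:
#'
#' * `psa.csv` — `patient_id,date,psa_ng_ml`
#' * `staging.csv` — `patient_id,tnm,gleason,prostate_volume_ml,life_expectancy_years`
#' * `treatments.csv` — `patient_id,modality,date,pre_treatment_psa_ng_ml`
#'
#' Dates are ISO-8601 (`YYYY-MM-DD`); empty cells mean "absent".
#'
#' @name records_io
NULL

T_CATEGORIES <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")
N_CATEGORIES <- c("N0", "N1", "NX")
M_CATEGORIES <- c("M0", "M1", "MX")
MODALITIES <- c("surgery", "radiotherapy", "hormonal", "chemotherapy",
                "watchful_waiting")

#' Parse a TNM staging string
#'
#' Parses strings such as `"T2cN0M0"` into a tumor/node/metastasis triple.
#' The tumor axis uses the nine prostate substages `T1a`–`T4`; nodes are
#' `N0`/`N1` and metastases `M0`/`M1`. Components not present in the string
#' parse as `NX`/`MX` ("not assessed") — absence of evidence is recorded,
#' never assumed to be `N0`/`M0`.
#'
#' @param text A staging string, e.g. `"T2cN0M0"` or bare `"T1c"`.
#' @return An object of class `clinical_stage`: a list with components
#'   `t_category`, `n_category`, `m_category`.
#' @examples
#' parse_tnm("T2cN0M0")
#' parse_tnm("T1c")  # N and M default to NX/MX
#' @export
parse_tnm <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop_data("TNM stage string must be a single non-empty string")
  }
  s <- gsub("\\s+", "", text)
  m <- regmatches(s, regexec("^(T[0-9][a-c]?)(N[01X])?(M[01X])?$", s,
                             ignore.case = TRUE))[[1]]
  if (length(m) == 0L) {
    stop_data("malformed TNM stage string: '%s'", text)
  }
  # normalise case: "T" and digit upper, substage letter lower
  t_cat <- paste0(toupper(substr(m[2], 1, 2)), tolower(substring(m[2], 3)))
  if (!t_cat %in% T_CATEGORIES) {
    stop_data("unknown T category '%s' in '%s'", t_cat, text)
  }
  n_cat <- if (is.na(m[3]) || !nzchar(m[3])) "NX" else toupper(m[3])
  m_cat <- if (is.na(m[4]) || !nzchar(m[4])) "MX" else toupper(m[4])
  structure(list(t_category = t_cat, n_category = n_cat, m_category = m_cat),
            class = "clinical_stage")
}

#' @export
print.clinical_stage <- function(x, ...) {
  cat(sprintf("<clinical_stage> %s %s %s\n",
              x$t_category, x$n_category, x$m_category))
  invisible(x)
}

#' @export
format.clinical_stage <- function(x, ...) {
  paste0(x$t_category,
         if (x$n_category != "NX") x$n_category else "",
         if (x$m_category != "MX") x$m_category else "")
}

#' Parse a Gleason score
#'
#' Accepts the three notations found in clinical records: a pattern pair
#' `"4+3"` (primary + secondary grade, each 1–5), a bare sum `"7"`, or a sum
#' range `"5-6"`. The histological sum is always between 2 and 10; pattern
#' grades are retained when given, and a range yields a set of plausible
#' sums with patterns absent.
#'
#' @param text Score string: `"a+b"`, `"s"`, or `"a-b"`.
#' @return An object of class `gleason_score` with components `primary`,
#'   `secondary` (integer or `NA`) and `sum_set` (integer vector of
#'   plausible sums).
#' @examples
#' parse_gleason("4+3")
#' parse_gleason("5-6")
#' @export
parse_gleason <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop_data("Gleason score string must be a single non-empty string")
  }
  s <- gsub("\\s+", "", text)
  if (grepl("^[0-9]+\\+[0-9]+$", s)) {
    parts <- as.integer(strsplit(s, "+", fixed = TRUE)[[1]])
    if (any(parts < 1L | parts > 5L)) {
      stop_data("Gleason pattern grades must lie in 1..5: '%s'", text)
    }
    return(new_gleason(parts[1], parts[2], parts[1] + parts[2]))
  }
  if (grepl("^[0-9]+-[0-9]+$", s)) {
    parts <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
    if (parts[1] > parts[2]) {
      stop_data("Gleason sum range reversed: '%s'", text)
    }
    sums <- seq.int(parts[1], parts[2])
    if (any(sums < 2L | sums > 10L)) {
      stop_data("Gleason sums must lie in 2..10: '%s'", text)
    }
    return(new_gleason(NA_integer_, NA_integer_, sums))
  }
  if (grepl("^[0-9]+$", s)) {
    sum <- as.integer(s)
    if (sum < 2L || sum > 10L) {
      stop_data("Gleason sum must lie in 2..10: '%s'", text)
    }
    return(new_gleason(NA_integer_, NA_integer_, sum))
  }
  stop_data("unrecognised Gleason notation: '%s'", text)
}

new_gleason <- function(primary, secondary, sum_set) {
  structure(list(primary = primary, secondary = secondary,
                 sum_set = as.integer(sum_set)),
            class = "gleason_score")
}

#' @export
print.gleason_score <- function(x, ...) {
  cat(sprintf("<gleason_score> %s (sum%s %s)\n",
              if (is.na(x$primary)) "patterns unknown"
              else paste0(x$primary, "+", x$secondary),
              if (length(x$sum_set) > 1L) "s" else "",
              paste(x$sum_set, collapse = ",")))
  invisible(x)
}

#' @export
format.gleason_score <- function(x, ...) {
  if (!is.na(x$primary)) return(paste0(x$primary, "+", x$secondary))
  if (length(x$sum_set) > 1L) {
    return(paste0(min(x$sum_set), "-", max(x$sum_set)))
  }
  as.character(x$sum_set)
}

# Worst-case sum used wherever a single grade must be compared to a
# criterion (a range like "5-6" matches via its maximum element).
gleason_max <- function(gleason) {
  if (is.null(gleason)) return(NA_integer_)
  max(gleason$sum_set)
}

#' Construct a PSA measurement series
#'
#' @param patient_id Non-empty identifier.
#' @param dates Measurement dates (`Date` or `YYYY-MM-DD` strings).
#' @param psa PSA concentrations, ng/mL, all non-negative.
#' @return A `psa_series`: measurements sorted ascending by date.
#' @export
psa_series <- function(patient_id, dates, psa) {
  if (!nzchar(patient_id)) stop_data("patient_id must be non-empty")
  dates <- parse_date(as.character(dates), "PSA measurement date")
  psa <- as.numeric(psa)
  if (length(dates) != length(psa)) {
    stop_data("dates and psa lengths differ for patient %s", patient_id)
  }
  if (anyNA(psa) || any(psa < 0)) {
    stop_data("PSA values must be non-negative numbers (patient %s)",
              patient_id)
  }
  if (anyDuplicated(dates)) {
    stop_data("duplicate PSA measurement date for patient %s: %s",
              patient_id,
              paste(unique(dates[duplicated(dates)]), collapse = ", "))
  }
  o <- order(dates)
  structure(list(patient_id = patient_id,
                 measurements = data.frame(date = dates[o], psa = psa[o])),
            class = "psa_series")
}

#' @export
print.psa_series <- function(x, ...) {
  n <- nrow(x$measurements)
  cat(sprintf("<psa_series> patient %s: %d measurement%s", x$patient_id, n,
              if (n == 1L) "" else "s"))
  if (n > 0L) {
    cat(sprintf(" (%s to %s, PSA %.2f to %.2f ng/mL)",
                min(x$measurements$date), max(x$measurements$date),
                min(x$measurements$psa), max(x$measurements$psa)))
  }
  cat("\n")
  invisible(x)
}

#' Construct a treatment event
#'
#' @param modality One of `surgery`, `radiotherapy`, `hormonal`,
#'   `chemotherapy`, `watchful_waiting`.
#' @param date Treatment date.
#' @param pre_treatment_psa PSA immediately before treatment (ng/mL), or
#'   `NA` when unknown.
#' @export
treatment_event <- function(modality, date, pre_treatment_psa = NA_real_) {
  if (!modality %in% MODALITIES) {
    stop_data("unknown treatment modality '%s' (expected one of %s)",
              modality, paste(MODALITIES, collapse = ", "))
  }
  structure(list(modality = modality,
                 date = parse_date(as.character(date), "treatment date"),
                 pre_treatment_psa = as.numeric(pre_treatment_psa)),
            class = "treatment_event")
}

#' Construct a patient record
#'
#' @param patient_id Non-empty identifier.
#' @param psa_series A [psa_series()] (its `patient_id` must agree).
#' @param stage Optional [parse_tnm()] result.
#' @param gleason Optional [parse_gleason()] result.
#' @param prostate_volume Optional prostate volume, mL.
#' @param treatments List of [treatment_event()]s (sorted by date on
#'   construction).
#' @param life_expectancy Optional remaining life expectancy, years.
#' @export
patient_record <- function(patient_id, psa_series,
                           stage = NULL, gleason = NULL,
                           prostate_volume = NA_real_,
                           treatments = list(),
                           life_expectancy = NA_real_) {
  if (!nzchar(patient_id)) stop_data("patient_id must be non-empty")
  if (!identical(psa_series$patient_id, patient_id)) {
    stop_data("psa_series patient_id (%s) does not match record (%s)",
              psa_series$patient_id, patient_id)
  }
  if (length(treatments)) {
    treatments <- treatments[order(vapply(treatments,
                                          function(e) as.numeric(e$date),
                                          numeric(1)))]
  }
  structure(list(patient_id = patient_id,
                 psa_series = psa_series,
                 stage = stage,
                 gleason = gleason,
                 prostate_volume = as.numeric(prostate_volume),
                 treatments = treatments,
                 life_expectancy = as.numeric(life_expectancy)),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s\n", x$patient_id))
  cat(sprintf("  PSA measurements: %d\n", nrow(x$psa_series$measurements)))
  cat(sprintf("  stage: %s   Gleason: %s\n",
              if (is.null(x$stage)) "absent" else format(x$stage),
              if (is.null(x$gleason)) "absent" else format(x$gleason)))
  cat(sprintf("  prostate volume: %s mL   life expectancy: %s yr\n",
              if (is.na(x$prostate_volume)) "absent" else x$prostate_volume,
              if (is.na(x$life_expectancy)) "absent" else x$life_expectancy))
  if (length(x$treatments)) {
    for (tr in x$treatments) {
      cat(sprintf("  treatment: %s on %s\n", tr$modality, tr$date))
    }
  }
  invisible(x)
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop_data("%s: missing column(s) %s", path,
              paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), required_cols)
  if (length(extra)) {
    stop_data("%s: unknown column(s) %s", path, paste(extra, collapse = ", "))
  }
  df
}

num_or_na <- function(x) {
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read a cohort from delimited files
#'
#' Joins the three record files by `patient_id` and returns one
#' [patient_record()] per distinct id in the PSA file. Measurements are
#' sorted ascending by date; duplicate `(patient, date)` PSA rows are an
#' error, never silently averaged.
#'
#' @param psa_file,staging_file,treatment_file Paths to the delimited files
#'   (see [records_io] for the column contracts). `staging_file` and
#'   `treatment_file` may be `NULL` when absent.
#' @return A list of `patient_record`s (class `psa_cohort`), ordered by
#'   first appearance in the PSA file.
#' @export
read_cohort <- function(psa_file, staging_file = NULL, treatment_file = NULL) {
  psa <- read_csv_checked(psa_file, c("patient_id", "date", "psa_ng_ml"))
  dup <- duplicated(psa[c("patient_id", "date")])
  if (any(dup)) {
    stop_data("%s: duplicate (patient_id, date) row(s): %s", psa_file,
              paste(sprintf("(%s, %s)", psa$patient_id[dup], psa$date[dup]),
                    collapse = "; "))
  }
  psa_num <- num_or_na(psa$psa_ng_ml)
  if (nrow(psa) && anyNA(psa_num)) {
    stop_data("%s: non-numeric psa_ng_ml value(s)", psa_file)
  }

  staging <- NULL
  if (!is.null(staging_file)) {
    staging <- read_csv_checked(staging_file,
      c("patient_id", "tnm", "gleason", "prostate_volume_ml",
        "life_expectancy_years"))
    if (anyDuplicated(staging$patient_id)) {
      stop_data("%s: duplicate patient_id row(s)", staging_file)
    }
  }
  treatments <- NULL
  if (!is.null(treatment_file)) {
    treatments <- read_csv_checked(treatment_file,
      c("patient_id", "modality", "date", "pre_treatment_psa_ng_ml"))
  }

  ids <- unique(psa$patient_id)
  cohort <- lapply(ids, function(id) {
    rows <- psa$patient_id == id
    series <- psa_series(id, psa$date[rows], psa_num[rows])
    stage <- gleason <- NULL
    volume <- life_exp <- NA_real_
    if (!is.null(staging)) {
      srow <- staging[staging$patient_id == id, , drop = FALSE]
      if (nrow(srow) == 1L) {
        if (nzchar(srow$tnm)) stage <- parse_tnm(srow$tnm)
        if (nzchar(srow$gleason)) gleason <- parse_gleason(srow$gleason)
        volume <- num_or_na(srow$prostate_volume_ml)
        life_exp <- num_or_na(srow$life_expectancy_years)
      }
    }
    events <- list()
    if (!is.null(treatments)) {
      trows <- treatments[treatments$patient_id == id, , drop = FALSE]
      events <- lapply(seq_len(nrow(trows)), function(i) {
        treatment_event(trows$modality[i], trows$date[i],
                        num_or_na(trows$pre_treatment_psa_ng_ml[i]))
      })
    }
    patient_record(id, series, stage = stage, gleason = gleason,
                   prostate_volume = volume, treatments = events,
                   life_expectancy = life_exp)
  })
  structure(cohort, class = "psa_cohort")
}

#' @export
print.psa_cohort <- function(x, ...) {
  cat(sprintf("<psa_cohort> %d patient%s\n", length(x),
              if (length(x) == 1L) "" else "s"))
  invisible(x)
}

# 15 significant digits so numeric fields survive a write/read round trip
fmt_num <- function(x) {
  ifelse(is.na(x), "",
         format(x, trim = TRUE, scientific = FALSE, digits = 15))
}

#' Write a cohort to delimited files
#'
#' Emits `psa.csv`, `staging.csv` and `treatments.csv` under `out_dir` in
#' the formats [read_cohort()] reads; `read_cohort(write_cohort(c))`
#' reproduces `c` field for field. Absent values are written as empty cells.
#'
#' @param cohort A `psa_cohort` or plain list of `patient_record`s.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the three file paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa_rows <- do.call(rbind, c(list(
    data.frame(patient_id = character(), date = character(),
               psa_ng_ml = character())),
    lapply(cohort, function(r) {
      m <- r$psa_series$measurements
      data.frame(patient_id = rep(r$patient_id, nrow(m)),
                 date = format(m$date), psa_ng_ml = fmt_num(m$psa))
    })))
  staging_rows <- do.call(rbind, c(list(
    data.frame(patient_id = character(), tnm = character(),
               gleason = character(), prostate_volume_ml = character(),
               life_expectancy_years = character())),
    lapply(cohort, function(r) {
      data.frame(patient_id = r$patient_id,
                 tnm = if (is.null(r$stage)) "" else format(r$stage),
                 gleason = if (is.null(r$gleason)) "" else format(r$gleason),
                 prostate_volume_ml = fmt_num(r$prostate_volume),
                 life_expectancy_years = fmt_num(r$life_expectancy))
    })))
  treat_rows <- do.call(rbind, c(list(
    data.frame(patient_id = character(), modality = character(),
               date = character(), pre_treatment_psa_ng_ml = character())),
    lapply(cohort, function(r) {
      if (!length(r$treatments)) return(NULL)
      do.call(rbind, lapply(r$treatments, function(tr) {
        data.frame(patient_id = r$patient_id, modality = tr$modality,
                   date = format(tr$date),
                   pre_treatment_psa_ng_ml = fmt_num(tr$pre_treatment_psa))
      }))
    })))
  paths <- file.path(out_dir, c("psa.csv", "staging.csv", "treatments.csv"))
  utils::write.csv(psa_rows, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(staging_rows, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(treat_rows, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
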