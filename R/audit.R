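#' Post-treatment biochemical outcome auditing
#'
#' A treatment is counted as a biochemical success at a follow-up month
#' when the PSA measured near that visit is *less than* a
#' modality-specific threshold: 0.2 ng/mL after surgery, 2 ng/mL after
#' radiotherapy (strict inequality — a boundary value fails). A second,
#' modality-agnostic criterion asks only whether the PSA fell below its
#' pre-treatment value. [audit_cohort()] tabulates success fractions per
#' modality, criterion and follow-up month, with cell percentages rounded
#' half away from zero.
#'
#' Follow-up visits rarely land exactly on the nominal month, so the PSA
#' "at month m" is the measurement nearest to `treatment date + m months`
#' within ±45 days; a patient with no measurement in that window is not
#' evaluable at that month and drops out of the denominator.
#'
#' @name outcome_audit
NULL

#' Biochemical success thresholds
#'
#' @param surgery_threshold Post-surgery success threshold, ng/mL
#'   (default 0.2).
#' @param radiotherapy_threshold Post-radiotherapy success threshold,
#'   ng/mL (default 2).
#' @param window_days Half-width of the visit-matching window, days.
#' @export
outcome_criteria <- function(surgery_threshold = 0.2,
                             radiotherapy_threshold = 2.0,
                             window_days = 45) {
  if (surgery_threshold <= 0 || radiotherapy_threshold <= 0) {
    stop_domain("outcome thresholds must be positive")
  }
  structure(list(surgery_threshold = surgery_threshold,
                 radiotherapy_threshold = radiotherapy_threshold,
                 window_days = window_days),
            class = "outcome_criteria")
}

modality_threshold <- function(modality, criteria) {
  switch(modality,
         surgery = criteria$surgery_threshold,
         radiotherapy = criteria$radiotherapy_threshold,
         stop_domain("no success threshold is defined for modality '%s'",
                     modality))
}

# PSA measurement nearest to (event date + month), within the window;
# NA when none.
psa_at_month <- function(record, event, month, criteria) {
  target <- event$date + round(unit_to_days(month, "months"))
  m <- record$psa_series$measurements
  gap <- abs(as.numeric(m$date - target))
  ok <- gap <= criteria$window_days
  if (!any(ok)) return(NA_real_)
  m$psa[ok][which.min(gap[ok])]
}

#' Assess one treatment at one follow-up month
#'
#' @param record The [patient_record()] the event belongs to.
#' @param event A [treatment_event()] from `record$treatments`.
#' @param month Follow-up month (> 0).
#' @param criteria An [outcome_criteria()].
#' @param criterion `"threshold"` (modality-specific PSA cut-off; defined
#'   only for surgery and radiotherapy) or `"below_pretreatment"`.
#' @return `"success"`, `"failure"`, or `"not_evaluable"` (no measurement
#'   in the matching window, or missing pre-treatment PSA).
#' @export
assess_success <- function(record, event, month,
                           criteria = outcome_criteria(),
                           criterion = c("threshold", "below_pretreatment")) {
  criterion <- match.arg(criterion)
  if (month <= 0) stop_domain("follow-up month must be positive")
  psa <- psa_at_month(record, event, month, criteria)
  if (is.na(psa)) return("not_evaluable")
  if (criterion == "threshold") {
    thr <- modality_threshold(event$modality, criteria)
    return(if (psa < thr) "success" else "failure")
  }
  if (is.na(event$pre_treatment_psa)) return("not_evaluable")
  if (psa < event$pre_treatment_psa) "success" else "failure"
}

#' Audit a cohort's treatment outcomes
#'
#' For each audited modality, criterion and follow-up month, counts the
#' evaluable patients and those meeting the success criterion. Only the
#' first treatment of each audited modality per patient is audited.
#'
#' @param cohort A `psa_cohort` (or list of [patient_record()]s).
#' @param months Follow-up months (default `c(1, 3, 6, 9, 12)`).
#' @param criteria An [outcome_criteria()].
#' @return An `audit_table` data frame with columns `modality`,
#'   `criterion`, `month`, `successes`, `total`, `percent` (`NA` when no
#'   patient is evaluable).
#' @export
audit_cohort <- function(cohort, months = c(1, 3, 6, 9, 12),
                         criteria = outcome_criteria()) {
  if (!length(months)) stop_domain("months must be non-empty")
  modalities <- c("surgery", "radiotherapy")
  criteria_kinds <- c("threshold", "below_pretreatment")
  grid <- expand.grid(month = months, criterion = criteria_kinds,
                      modality = modalities, stringsAsFactors = FALSE)
  grid <- grid[, c("modality", "criterion", "month")]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    mod <- grid$modality[i]; crit <- grid$criterion[i]; mon <- grid$month[i]
    outcomes <- unlist(lapply(cohort, function(r) {
      ev <- Filter(function(e) e$modality == mod, r$treatments)
      if (!length(ev)) return(NULL)
      assess_success(r, ev[[1]], mon, criteria, crit)
    }))
    total <- sum(outcomes != "not_evaluable")
    successes <- sum(outcomes == "success")
    data.frame(modality = mod, criterion = crit, month = mon,
               successes = successes, total = total,
               percent = if (total > 0) summarize_counts(successes, total)
                         else NA_integer_)
  })
  out <- do.call(rbind, res)
  class(out) <- c("audit_table", class(out))
  out
}

#' Success percentage from counts
#'
#' `round(100 * successes / total)` with halves rounded away from zero —
#' the convention that reproduces published audit cells such as
#' 19/24 = 79%.
#'
#' @param successes,total Non-negative counts, `successes <= total`,
#'   `total > 0`.
#' @return Integer percentage in 0..100.
#' @examples
#' summarize_counts(29, 47) # 62
#' @export
summarize_counts <- function(successes, total) {
  if (any(total <= 0)) stop_domain("total must be positive")
  if (any(successes < 0 | successes > total)) {
    stop_domain("successes must lie in 0..total")
  }
  as.integer(floor(100 * successes / total + 0.5))
}

#' @export
print.audit_table <- function(x, ...) {
  months <- sort(unique(x$month))
  cat("<audit_table>  cells are successes/total(percent%)\n")
  hdr <- sprintf("%-14s %-20s %s", "modality", "criterion",
                 paste(sprintf("%10s", paste0("m", months)), collapse = ""))
  cat(hdr, "\n")
  for (mod in unique(x$modality)) {
    for (crit in unique(x$criterion)) {
      rows <- x[x$modality == mod & x$criterion == crit, , drop = FALSE]
      if (!nrow(rows) || all(rows$total == 0)) next
      cells <- vapply(months, function(m) {
        r <- rows[rows$month == m, , drop = FALSE]
        if (!nrow(r) || r$total == 0) return(sprintf("%10s", "-"))
        sprintf("%10s", sprintf("%d/%d(%d%%)", r$successes, r$total,
                                r$percent))
      }, character(1))
      cat(sprintf("%-14s %-20s %s\n", mod, crit, paste(cells, collapse = "")))
    }
  }
  invisible(x)
}
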