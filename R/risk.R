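#' D'Amico risk stratification and Partin-table lookup
#'
#' Pretreatment risk is stratified into three tiers from clinical T stage,
#' serum PSA and Gleason sum:
#'
#' * **low** — stage T1c or T2a *and* PSA <= 10 ng/mL *and* Gleason <= 6
#' * **intermediate** — stage T2b *or* Gleason = 7 *or* 10 < PSA <= 20
#' * **high** — stage T2c *or* PSA > 20 ng/mL *or* Gleason >= 8
#'
#' The tiers overlap (the intermediate and high rows are disjunctions), so
#' precedence is worst-first: high, then intermediate, then low — the worse
#' tier governs risk. Each tier carries a published outcome profile: a
#' 5-year PSA-failure risk band (<25 / 25–50 / >50 %) and 5- and 10-year
#' PSA-failure-free survival (85/83, 60/46, 30/29 %).
#'
#' A Gleason sum *range* (e.g. `"5-6"`) is compared to grade criteria via
#' its maximum element — the worst-case reading. Stages outside T1c–T2c
#' (T1a/T1b, T3, T4) are beyond the stratifier's domain; such patients are
#' `unclassified` unless PSA or Gleason alone trigger a tier.
#'
#' @name risk_stratification
NULL

RISK_GROUPS <- c("low", "intermediate", "high", "unclassified")

#' Read a risk-criteria table
#'
#' The packaged default transcribes the three-tier criteria and outcome
#' profile described in [risk_stratification]. Rows are evaluated in file
#' order (worst tier first). Each row's conditions are a stage set
#' (`t_stages`, semicolon-separated), a PSA interval (`psa_min` exclusive,
#' `psa_max` inclusive, empty = unbounded, matching the printed
#' inequalities "> 10 and <= 20") and an inclusive Gleason-sum interval;
#' `logic` says whether *all* conditions must hold (conjunctive row) or
#' *any* (disjunctive row).
#'
#' @param file Path to a criteria CSV; default is the packaged table.
#' @return A data frame of class `risk_criteria`.
#' @export
read_risk_criteria <- function(file = system.file("extdata",
                                                  "risk_criteria.csv",
                                                  package = "psakit")) {
  df <- utils::read.csv(file, colClasses = "character", strip.white = TRUE)
  needed <- c("group", "logic", "t_stages", "psa_min", "psa_max",
              "gleason_min", "gleason_max", "failure_lo", "failure_hi",
              "surv5", "surv10")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_data("risk criteria file %s: missing column(s) %s", file,
              paste(missing, collapse = ", "))
  }
  num_cols <- c("psa_min", "psa_max", "gleason_min", "gleason_max",
                "failure_lo", "failure_hi", "surv5", "surv10")
  for (cl in num_cols) df[[cl]] <- num_or_na(df[[cl]])
  if (!all(df$logic %in% c("all", "any"))) {
    stop_data("risk criteria: logic must be 'all' or 'any'")
  }
  class(df) <- c("risk_criteria", class(df))
  df
}

criteria_row_matches <- function(row, t_category, psa, gmax) {
  conds <- logical(0)
  if (nzchar(row$t_stages)) {
    stages <- strsplit(row$t_stages, ";", fixed = TRUE)[[1]]
    conds <- c(conds, t_category %in% stages)
  }
  if (!is.na(row$psa_min) || !is.na(row$psa_max)) {
    lo <- if (is.na(row$psa_min)) -Inf else row$psa_min
    hi <- if (is.na(row$psa_max)) Inf else row$psa_max
    conds <- c(conds, psa > lo && psa <= hi)
  }
  if (!is.na(row$gleason_min) || !is.na(row$gleason_max)) {
    lo <- if (is.na(row$gleason_min)) -Inf else row$gleason_min
    hi <- if (is.na(row$gleason_max)) Inf else row$gleason_max
    conds <- c(conds, gmax >= lo && gmax <= hi)
  }
  if (!length(conds)) return(FALSE)
  if (row$logic == "all") all(conds) else any(conds)
}

#' Assign a patient to a risk tier
#'
#' @param stage A [parse_tnm()] result (or a TNM string).
#' @param psa Serum PSA, ng/mL (non-negative).
#' @param gleason A [parse_gleason()] result (or a score string).
#' @param criteria A [read_risk_criteria()] table; packaged default.
#' @return One of `"high"`, `"intermediate"`, `"low"`, `"unclassified"`.
#' @examples
#' stratify(parse_tnm("T1c"), 32.4, parse_gleason("5-6")) # "high"
#' @export
stratify <- function(stage, psa, gleason, criteria = read_risk_criteria()) {
  if (is.character(stage)) stage <- parse_tnm(stage)
  if (is.character(gleason)) gleason <- parse_gleason(gleason)
  if (is.na(psa) || psa < 0) stop_domain("PSA must be non-negative")
  gmax <- gleason_max(gleason)
  if (is.na(gmax)) stop_domain("Gleason sum set must be non-empty")
  for (i in seq_len(nrow(criteria))) {
    if (criteria_row_matches(criteria[i, , drop = FALSE],
                             stage$t_category, psa, gmax)) {
      return(criteria$group[i])
    }
  }
  "unclassified"
}

#' Outcome profile of a risk tier
#'
#' Returns the published outcome row for a tier: the 5-year PSA-failure
#' risk band and the 5- and 10-year PSA-failure-free survival percentages.
#'
#' @param group `"low"`, `"intermediate"` or `"high"` (an `"unclassified"`
#'   patient has no profile and raises an error).
#' @inheritParams stratify
#' @return A `risk_profile` list: `group`, `failure_band_pct`
#'   (length-2 numeric, `-Inf`/`Inf` for open ends), `survival_5yr_pct`,
#'   `survival_10yr_pct`.
#' @examples
#' risk_profile("high") # failure band (50, Inf), survival 30 / 29 %
#' @export
risk_profile <- function(group, criteria = read_risk_criteria()) {
  if (!group %in% criteria$group) {
    stop_domain("no outcome profile for risk group '%s'", group)
  }
  row <- criteria[criteria$group == group, , drop = FALSE][1, ]
  structure(list(
    group = group,
    failure_band_pct = c(if (is.na(row$failure_lo)) -Inf else row$failure_lo,
                         if (is.na(row$failure_hi)) Inf else row$failure_hi),
    survival_5yr_pct = row$surv5,
    survival_10yr_pct = row$surv10),
    class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  band <- x$failure_band_pct
  band_txt <- if (is.infinite(band[1])) {
    sprintf("< %g%%", band[2])
  } else if (is.infinite(band[2])) {
    sprintf("> %g%%", band[1])
  } else sprintf("%g-%g%%", band[1], band[2])
  cat(sprintf("<risk_profile> %s risk\n", x$group))
  cat(sprintf("  5-yr PSA failure: %s\n", band_txt))
  cat(sprintf("  PSA failure-free survival: %g%% (5 yr), %g%% (10 yr)\n",
              x$survival_5yr_pct, x$survival_10yr_pct))
  invisible(x)
}

#' Read a Partin pathologic-stage table
#'
#' A Partin table maps (clinical T stage, PSA range, Gleason range) to
#' probabilities of final pathologic stage. Published editions are not
#' redistributed here: the packaged fixture `partin_synthetic.csv` is a
#' synthetic stand-in with plausible magnitudes, intended to be replaced by
#' a file in the same schema transcribed from a published edition.
#'
#' Columns: `t_category`, `psa_min`, `psa_max` (lower-closed, upper-open
#' interval; empty `psa_max` = unbounded), `gleason_min`, `gleason_max`
#' (inclusive), then one `*_pct` column per pathologic stage.
#'
#' @param file Path to a Partin CSV; default is the synthetic fixture.
#' @return A data frame of class `partin_table`.
#' @export
read_partin_table <- function(file = system.file("extdata",
                                                 "partin_synthetic.csv",
                                                 package = "psakit")) {
  df <- utils::read.csv(file, colClasses = "character", strip.white = TRUE)
  key_cols <- c("t_category", "psa_min", "psa_max", "gleason_min",
                "gleason_max")
  missing <- setdiff(key_cols, names(df))
  if (length(missing)) {
    stop_data("Partin table %s: missing column(s) %s", file,
              paste(missing, collapse = ", "))
  }
  prob_cols <- setdiff(names(df), key_cols)
  if (!length(prob_cols)) {
    stop_data("Partin table %s has no probability columns", file)
  }
  for (cl in setdiff(key_cols, "t_category")) df[[cl]] <- num_or_na(df[[cl]])
  for (cl in prob_cols) {
    df[[cl]] <- num_or_na(df[[cl]])
    if (any(df[[cl]] < 0 | df[[cl]] > 100, na.rm = TRUE)) {
      stop_data("Partin table %s: probabilities must lie in [0,100]", file)
    }
  }
  attr(df, "prob_cols") <- prob_cols
  class(df) <- c("partin_table", class(df))
  df
}

#' Look up pathologic-stage probabilities in a Partin table
#'
#' PSA intervals are lower-closed and upper-open, so a PSA exactly on a
#' boundary falls in the higher cell. Gleason ranges in the record match a
#' cell via their maximum sum.
#'
#' @param table A [read_partin_table()] result.
#' @inheritParams stratify
#' @return Named numeric vector of pathologic-stage probabilities (%),
#'   returned verbatim from the matching cell.
#' @export
partin_lookup <- function(table, stage, psa, gleason) {
  if (is.character(stage)) stage <- parse_tnm(stage)
  if (is.character(gleason)) gleason <- parse_gleason(gleason)
  gmax <- gleason_max(gleason)
  lo <- ifelse(is.na(table$psa_min), -Inf, table$psa_min)
  hi <- ifelse(is.na(table$psa_max), Inf, table$psa_max)
  hit <- table$t_category == stage$t_category &
    psa >= lo & psa < hi &
    gmax >= table$gleason_min & gmax <= table$gleason_max
  if (!any(hit)) {
    stop_data(
      "(%s, PSA %g, Gleason %d) is not covered by this Partin table",
      stage$t_category, psa, gmax)
  }
  row <- table[which(hit)[1], , drop = FALSE]
  out <- as.numeric(row[attr(table, "prob_cols")])
  names(out) <- attr(table, "prob_cols")
  out
}
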