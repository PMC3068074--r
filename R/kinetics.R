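#' PSA kinetics: velocity, doubling time, density
#'
#' Pretreatment PSA dynamics are summarised by three parameters, each
#' estimable by two algorithms:
#'
#' * **PSA velocity (PSAV)** — slope of the linear model
#'   `PSA = initial PSA + PSAV * t`, fitted by ordinary least squares over a
#'   measurement window ([psav_regression()]), or the secant slope through
#'   two chosen markers ([psav_two_marker()]). Reported in ng/mL per year by
#'   default, matching the 0.75 and 2 ng/mL/yr clinical cut-offs.
#' * **PSA doubling time (PSADT)** — under exponential growth, `ln(PSA)` is
#'   linear in time and the doubling time is `ln(2)/slope`. Estimated by OLS
#'   on the log scale ([psadt_regression()]) or from two markers as
#'   `(t2 - t1) * ln(2) / ln(p2/p1)` ([psadt_two_marker()]). Months by
#'   default. A non-increasing PSA has no doubling time: reported as `NA`
#'   ("undefined"), never as a negative number.
#' * **PSA density (PSAD)** — PSA divided by prostate volume ([psad()]).
#'
#' @name psa_kinetics
NULL

#' Select a kinetics window from a PSA series
#'
#' @param series A [psa_series()].
#' @param from,to Optional date bounds (inclusive) restricting the window.
#' @param time_unit Unit in which elapsed time is measured for velocity
#'   fits: `"days"`, `"months"` or `"years"` (default).
#' @return A `kinetics_window`: the selected measurements with elapsed time
#'   anchored at the first selected date (`t_origin`), so the regression
#'   intercept is the "initial PSA" at the window start.
#' @export
kinetics_window <- function(series, from = NULL, to = NULL,
                            time_unit = "years") {
  time_unit <- match.arg(time_unit, TIME_UNITS)
  m <- series$measurements
  if (!is.null(from)) m <- m[m$date >= as.Date(from), , drop = FALSE]
  if (!is.null(to)) m <- m[m$date <= as.Date(to), , drop = FALSE]
  if (nrow(m) < 2L) {
    stop_domain("kinetics window needs at least 2 measurements (got %d)",
                nrow(m))
  }
  structure(list(measurements = m, t_origin = m$date[1],
                 time_unit = time_unit),
            class = "kinetics_window")
}

new_kinetics_result <- function(initial_psa, psav, psadt, n_points, method,
                                time_unit, psadt_unit) {
  structure(list(initial_psa = initial_psa, psav = psav, psadt = psadt,
                 n_points = n_points, method = method,
                 time_unit = time_unit, psadt_unit = psadt_unit),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("<kinetics_result> (%s, n = %d)\n", x$method, x$n_points))
  if (!is.na(x$initial_psa)) {
    cat(sprintf("  initial PSA: %.4g ng/mL\n", x$initial_psa))
  }
  if (!is.na(x$psav)) {
    cat(sprintf("  PSAV: %.4g ng/mL per %s\n", x$psav,
                sub("s$", "", x$time_unit)))
  }
  cat(sprintf("  PSADT: %s\n",
              if (is.na(x$psadt)) "undefined (PSA not rising)"
              else sprintf("%.4g %s", x$psadt, x$psadt_unit)))
  invisible(x)
}

#' PSA velocity by linear regression
#'
#' Ordinary least-squares fit of PSA against elapsed time from the window
#' origin. The slope is the velocity and the intercept the initial PSA.
#'
#' @param window A [kinetics_window()].
#' @return A `kinetics_result` with `psav` in ng/mL per `window$time_unit`.
#' @export
psav_regression <- function(window) {
  m <- window$measurements
  t <- elapsed(m$date, window$t_origin, window$time_unit)
  fit <- stats::lm(psa ~ t, data = data.frame(psa = m$psa, t = t))
  co <- stats::coef(fit)
  new_kinetics_result(initial_psa = unname(co[1]), psav = unname(co[2]),
                      psadt = NA_real_, n_points = nrow(m),
                      method = "regression",
                      time_unit = window$time_unit, psadt_unit = NA_character_)
}

#' PSA velocity from two markers
#'
#' Secant slope through two chosen measurements:
#' `(p2 - p1) / (t2 - t1)`. With exactly two points this equals the OLS
#' slope.
#'
#' @param p1,p2 PSA at the earlier and later marker, ng/mL.
#' @param t1,t2 Times of the markers (any consistent unit); `t2 > t1`.
#' @return Velocity in ng/mL per time unit.
#' @export
psav_two_marker <- function(p1, t1, p2, t2) {
  if (t2 <= t1) stop_domain("marker times must satisfy t2 > t1")
  (p2 - p1) / (t2 - t1)
}

#' PSA doubling time by log-linear regression
#'
#' Fits `ln(PSA)` against elapsed time by OLS; the doubling time is
#' `ln(2)` divided by the slope. A slope `<= 0` (PSA not rising) yields an
#' undefined doubling time, reported as `NA`.
#'
#' @param window A [kinetics_window()]; all PSA values must be positive.
#' @param unit Unit for the doubling time (default `"months"`).
#' @return A `kinetics_result` with `psadt` in `unit` (or `NA`).
#' @export
psadt_regression <- function(window, unit = "months") {
  unit <- match.arg(unit, TIME_UNITS)
  m <- window$measurements
  if (any(m$psa <= 0)) {
    stop_domain(
      "doubling time requires strictly positive PSA (logarithm undefined)")
  }
  t <- elapsed(m$date, window$t_origin, unit)
  fit <- stats::lm(lp ~ t, data = data.frame(lp = log(m$psa), t = t))
  slope <- unname(stats::coef(fit)[2])
  psadt <- if (slope <= 0) NA_real_ else log(2) / slope
  new_kinetics_result(initial_psa = exp(unname(stats::coef(fit)[1])),
                      psav = NA_real_, psadt = psadt, n_points = nrow(m),
                      method = "regression",
                      time_unit = unit, psadt_unit = unit)
}

#' PSA doubling time from two markers
#'
#' Interpolates the line through `(t1, ln p1)` and `(t2, ln p2)`:
#' the doubling time is `(t2 - t1) * ln(2) / ln(p2 / p1)`. When
#' `p2 <= p1` (PSA not rising) the doubling time is undefined (`NA`).
#'
#' @param p1,p2 Positive PSA at the earlier and later marker, ng/mL.
#' @param t1,t2 Marker times (any consistent unit); `t2 > t1`.
#' @return Doubling time in the unit of `t1`/`t2`, or `NA`.
#' @export
psadt_two_marker <- function(p1, t1, p2, t2) {
  if (p1 <= 0 || p2 <= 0) {
    stop_domain("doubling time requires strictly positive PSA")
  }
  if (t2 <= t1) stop_domain("marker times must satisfy t2 > t1")
  if (p2 <= p1) return(NA_real_)
  (t2 - t1) * log(2) / log(p2 / p1)
}

#' PSA density
#'
#' @param psa PSA concentration, ng/mL.
#' @param prostate_volume Prostate volume, mL; must be positive.
#' @return PSA density, ng/mL per mL.
#' @examples
#' psad(4.0, 40) # 0.10
#' @export
psad <- function(psa, prostate_volume) {
  if (is.null(prostate_volume) || is.na(prostate_volume) ||
      prostate_volume <= 0) {
    stop_domain("PSA density requires a positive prostate volume")
  }
  psa / prostate_volume
}

#' Flag a PSA velocity against a clinical cut-off
#'
#' A velocity *in excess of* the cut-off is flagged: the comparison is
#' strict, so a velocity exactly at the cut-off is not flagged. The default
#' cut-off is 0.75 ng/mL/yr; 2 ng/mL/yr is the commonly used alternative.
#'
#' @param psav Velocity, ng/mL per year.
#' @param cutoff Positive cut-off, ng/mL per year.
#' @return `TRUE` iff `psav > cutoff`.
#' @export
flag_velocity <- function(psav, cutoff = 0.75) {
  if (cutoff <= 0) stop_domain("velocity cut-off must be positive")
  psav > cutoff
}
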