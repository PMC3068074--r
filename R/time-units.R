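# Calendar arithmetic. Elapsed time between dates is computed in days and
# converted with the usual astronomical-year conventions; these constants
# are used everywhere dates meet the kinetics formulas so the package has a
# single notion of "a month".

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.44

TIME_UNITS <- c("days", "months", "years")

# days -> unit
days_to_unit <- function(days, unit) {
  unit <- match.arg(unit, TIME_UNITS)
  switch(unit,
         days = days,
         months = days / DAYS_PER_MONTH,
         years = days / DAYS_PER_YEAR)
}

unit_to_days <- function(x, unit) {
  unit <- match.arg(unit, TIME_UNITS)
  switch(unit,
         days = x,
         months = x * DAYS_PER_MONTH,
         years = x * DAYS_PER_YEAR)
}

# Elapsed time from `origin` to each element of `dates`, in `unit`.
elapsed <- function(dates, origin, unit = "years") {
  days_to_unit(as.numeric(as.Date(dates) - as.Date(origin)), unit)
}

parse_date <- function(x, context = "date") {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(d) & !is.na(x) & nzchar(x)
  if (any(bad)) {
    stop_data("unparseable %s (expected YYYY-MM-DD): %s",
              context, paste(unique(x[bad]), collapse = ", "))
  }
  d
}
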