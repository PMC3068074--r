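# Structured conditions so the CLI can map error families to exit codes:
# usage (bad flags), data (unparseable/invalid input), domain (operation
# undefined for these values, e.g. PSAD without a prostate volume).

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("psakit_usage_error", "psakit_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("psakit_data_error", "psakit_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("psakit_domain_error", "psakit_error")))
}

#' @keywords internal
"_PACKAGE"
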