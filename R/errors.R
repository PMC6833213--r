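## Classed conditions so callers (and the command-line wrapper) can map
## failure modes to distinct exit codes.

stopInvalidInput <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("coursense_invalid_input", "coursense_error")))
}

stopParse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("coursense_parse_error", "coursense_error")))
}

stopDegenerateFit <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("coursense_degenerate_fit", "coursense_error")))
}

stopInvalidModel <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("coursense_invalid_model", "coursense_error")))
}

warnDataQuality <- function(fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c("coursense_data_quality", "coursense_warning")))
}
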