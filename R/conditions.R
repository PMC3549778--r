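# Classed conditions so callers (the scan driver, the CLI) can distinguish
# bad inputs from data that are merely untestable.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("levenemct_invalid_input", "levenemct_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("levenemct_degenerate_data", "levenemct_error")))
}

stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("levenemct_parse_error", "levenemct_error")))
}
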