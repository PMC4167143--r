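# Classed conditions so callers (and the CLI) can distinguish bad input
# from internal defects.

abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("alignoise_input_error", "error")))
}

abort_internal <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("alignoise_internal_error", "error")))
}

abort_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("alignoise_degenerate_error",
                                "alignoise_input_error", "error")))
}
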