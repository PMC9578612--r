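# Classed conditions so callers (and tests) can distinguish bad input files,
# degenerate data, configuration mistakes and internal assertion failures.

dscn_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dscn_error", "error", "condition")))
}

dscn_format_error     <- function(msg) dscn_abort(msg, "dscn_format_error")
dscn_input_error      <- function(msg) dscn_abort(msg, "dscn_input_error")
dscn_degenerate_error <- function(msg) dscn_abort(msg, "dscn_degenerate_error")
dscn_config_error     <- function(msg) dscn_abort(msg, "dscn_config_error")
dscn_internal_error   <- function(msg) dscn_abort(msg, "dscn_internal_error")

dscn_warn <- function(msg) {
  warning(warningCondition(msg, class = c("dscn_warning", "warning", "condition")))
}
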