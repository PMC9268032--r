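# Classed conditions so callers (and the CLI) can distinguish failure modes.
abort_monolayer <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "monolayer_error"), call = call))
}

abort_format       <- function(msg) abort_monolayer(msg, "monolayer_format_error")
abort_parse        <- function(msg) abort_monolayer(msg, "monolayer_parse_error")
abort_insufficient <- function(msg) abort_monolayer(msg, "monolayer_insufficient_data_error")
abort_param        <- function(msg) abort_monolayer(msg, "monolayer_parameter_error")
abort_range        <- function(msg) abort_monolayer(msg, "monolayer_range_error")
abort_domain       <- function(msg) abort_monolayer(msg, "monolayer_domain_error")
abort_io           <- function(msg) abort_monolayer(msg, "monolayer_io_error")
abort_spec         <- function(msg) abort_monolayer(msg, "monolayer_spec_error")
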