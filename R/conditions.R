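# Classed conditions so callers (and tests) can distinguish failure modes.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "airwayspec_error", "error")))
}

abort_format     <- function(msg) abort(msg, "airwayspec_format_error")
abort_validation <- function(msg) abort(msg, "airwayspec_validation_error")
abort_range      <- function(msg) abort(msg, "airwayspec_range_error")
abort_parameter  <- function(msg) abort(msg, "airwayspec_parameter_error")
abort_reference  <- function(msg) abort(msg, "airwayspec_reference_error")
abort_normalize  <- function(msg) abort(msg, "airwayspec_normalization_error")
abort_fit        <- function(msg) abort(msg, "airwayspec_fit_error")
abort_state      <- function(msg) abort(msg, "airwayspec_state_error")
abort_io         <- function(msg) abort(msg, "airwayspec_io_error")
abort_empty      <- function(msg) abort(msg, "airwayspec_empty_cohort_error")
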