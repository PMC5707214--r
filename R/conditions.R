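# Classed conditions so callers can distinguish failure modes programmatically.

abort_fpcit <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fpcit_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_invalid_parameter <- function(msg) abort_fpcit(msg, "fpcit_invalid_parameter")
stop_invalid_geometry  <- function(msg) abort_fpcit(msg, "fpcit_invalid_geometry")
stop_insufficient_comparators <- function(msg) abort_fpcit(msg, "fpcit_insufficient_comparators")
stop_degenerate_regression <- function(msg) abort_fpcit(msg, "fpcit_degenerate_regression")
stop_degenerate_reference  <- function(msg) abort_fpcit(msg, "fpcit_degenerate_reference")
stop_missing_input   <- function(msg) abort_fpcit(msg, "fpcit_missing_input")
stop_configuration   <- function(msg) abort_fpcit(msg, "fpcit_configuration")
stop_insufficient_data <- function(msg) abort_fpcit(msg, "fpcit_insufficient_data")
stop_invalid_input   <- function(msg) abort_fpcit(msg, "fpcit_invalid_input")
stop_stratification  <- function(msg) abort_fpcit(msg, "fpcit_stratification")
stop_undefined_metric <- function(msg) abort_fpcit(msg, "fpcit_undefined_metric")

`%||%` <- function(a, b) if (is.null(a)) b else a
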