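#' @keywords internal
#' Classed conditions so callers can distinguish failure modes.
#' All errors inherit "comboDE_error"; the subclass names the contract broken.
stop_combo <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "comboDE_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

format_error        <- function(msg) stop_combo("comboDE_format_error", msg)
consistency_error   <- function(msg) stop_combo("comboDE_consistency_error", msg)
parameter_error     <- function(msg) stop_combo("comboDE_parameter_error", msg)
normalization_error <- function(msg) stop_combo("comboDE_normalization_error", msg)
design_error        <- function(msg) stop_combo("comboDE_design_error", msg)
domain_error        <- function(msg) stop_combo("comboDE_domain_error", msg)
numeric_error       <- function(msg) stop_combo("comboDE_numeric_error", msg)
input_error         <- function(msg) stop_combo("comboDE_input_error", msg)
io_error            <- function(msg) stop_combo("comboDE_io_error", msg)
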