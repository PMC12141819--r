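# Condition classes shared across the package. Every declared failure mode
# signals a classed condition so callers (and the CLI) can react without
# string-matching messages.

mf_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("midflux_", class), "midflux_error"), ...)
}

mf_warn <- function(message, class, ...) {
  warn(message, class = c(paste0("midflux_", class), "midflux_warning"), ...)
}

stop_invalid_measurement <- function(msg, ...) mf_abort(msg, "invalid_measurement", ...)
stop_empty_measurement   <- function(msg, ...) mf_abort(msg, "empty_measurement", ...)
stop_domain              <- function(msg, ...) mf_abort(msg, "domain_error", ...)
stop_shape               <- function(msg, ...) mf_abort(msg, "shape_error", ...)
stop_composition         <- function(msg, ...) mf_abort(msg, "composition_error", ...)
stop_unreliable_labeling <- function(msg, ...) mf_abort(msg, "unreliable_labeling", ...)
stop_division_unstable   <- function(msg, ...) mf_abort(msg, "division_unstable", ...)
stop_singular_system     <- function(msg, ...) mf_abort(msg, "singular_system", ...)
stop_incomplete_design   <- function(msg, ...) mf_abort(msg, "incomplete_design", ...)
stop_config              <- function(msg, ...) mf_abort(msg, "config_error", ...)
stop_format              <- function(msg, ...) mf_abort(msg, "format_error", ...)
stop_parse               <- function(msg, ...) mf_abort(msg, "parse_error", ...)
stop_ordering            <- function(msg, ...) mf_abort(msg, "ordering_error", ...)
stop_usage               <- function(msg, ...) mf_abort(msg, "usage_error", ...)
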