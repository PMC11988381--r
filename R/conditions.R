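# Classed error conditions used across the pipeline. Each abort_* helper
# raises a condition inheriting from c("edcscreen_<class>", "edcscreen_error",
# "error"), so callers can catch a specific failure mode.

abort_edc <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("edcscreen_", class), "edcscreen_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_parse  <- function(msg) abort_edc("parse_error", msg)
abort_format <- function(msg) abort_edc("format_error", msg)
abort_domain <- function(msg) abort_edc("domain_error", msg)
abort_key    <- function(msg) abort_edc("key_error", msg)
abort_config <- function(msg) abort_edc("config_error", msg)
abort_adapter <- function(msg) abort_edc("adapter_error", msg)
abort_composition <- function(msg) abort_edc("composition_error", msg)
abort_empty_structure <- function(msg) abort_edc("empty_structure_error", msg)
abort_insufficient_data <- function(msg) abort_edc("insufficient_data_error", msg)
abort_unknown_residue <- function(msg) abort_edc("unknown_residue_error", msg)
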