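# data.table is used via :: only; declare awareness so [.data.table keeps
# data.table semantics inside this namespace.
.datatable.aware <- TRUE

# Classed conditions so callers can distinguish bad user input, unparseable
# files, broken configuration and aligner failures.

hc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hcorrect_error", "error")))
}

abort_validation <- function(msg) hc_abort(msg, "hcorrect_validation_error")
abort_parse      <- function(msg) hc_abort(msg, "hcorrect_parse_error")
abort_config     <- function(msg) hc_abort(msg, "hcorrect_config_error")
abort_aligner    <- function(msg) hc_abort(msg, "hcorrect_aligner_error")
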