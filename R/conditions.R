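# Classed conditions so the CLI can map failures to distinct exit codes.

abort_io <- function(message, ...) {
  rlang::abort(message, class = c("flfa_error_io", "flfa_error"), ...)
}

abort_config <- function(message, ...) {
  rlang::abort(message, class = c("flfa_error_config", "flfa_error"), ...)
}

abort_processing <- function(message, ...) {
  rlang::abort(message, class = c("flfa_error_processing", "flfa_error"), ...)
}
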