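#' @keywords internal
"_PACKAGE"

# Package-level message logging.  Filtering and imputation steps report
# in/out counts through here so that survivorship is auditable; silence with
# options(hybridforge.verbose = FALSE).
hf_log <- function(...) {
  if (isTRUE(getOption("hybridforge.verbose", TRUE))) {
    message("[hybridforge] ", ...)
  }
}

# Stop with a consistent error prefix.
hf_stop <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
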