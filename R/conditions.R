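# Condition classes used across the package. Validation failures (bad trees,
# bad compositions) are distinguishable from I/O failures so the CLI can map
# them to distinct exit codes.

stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("jellyplot_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_io <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("jellyplot_io_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
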