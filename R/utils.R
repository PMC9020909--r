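## Internal helpers shared across modules.

## Classed conditions so callers (and tests) can catch specific failure
## modes, e.g. expect_error(..., class = "EventError").
ffStop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "fearfuseError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

ffWarn <- function(class, msg) {
  warning(structure(
    class = c(class, "fearfuseWarning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

## Power floor applied before logs (zero band power, zero projected
## variance). Kept well below any physical EEG power in uV^2.
.POWER_FLOOR <- 1e-20

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## format a double so it round-trips bit-exactly through text
formatExact <- function(x) sprintf("%.17g", x)
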