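#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can react to specific pipeline failures.
# Every error signalled by the package carries class c(<specific>, "wm_error").
wm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "wm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

wm_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
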