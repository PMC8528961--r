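#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed abort: every validation failure in the package raises a condition
# subclassing "methclock_error" so callers can distinguish error families.
mc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "methclock_error")))
}

mc_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "methclock_warning")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    mc_abort(sprintf("'%s' must be finite numeric", what),
             "methclock_validation_error")
  }
  invisible(x)
}
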