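`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is_scalar_number(x)) stopf("'%s' must be a single finite number", name)
  if (strict_lower) {
    if (x <= lower) stopf("'%s' must be > %s", name, lower)
  } else if (x < lower) {
    stopf("'%s' must be >= %s", name, lower)
  }
  if (x > upper) stopf("'%s' must be <= %s", name, upper)
  invisible(x)
}
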