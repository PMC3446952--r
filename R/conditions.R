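# Typed conditions used across the package.  Every user-facing error carries a
# subclass so callers (and the scan machinery) can distinguish a model-driven
# breakdown from a plain validation failure.

abort_retikin <- function(message, class, ...) {
  stop(structure(
    class = c(class, "retikin_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @noRd
abort_validation <- function(message, ...) {
  abort_retikin(message, class = "retikin_validation_error", ...)
}

# Chain breakdown: an approximation step produced a non-physical (negative or
# zero) concentration, e.g. residual transthyretin below total RBP4.
abort_chain_breakdown <- function(message, step, ...) {
  abort_retikin(message, class = "retikin_chain_breakdown", step = step, ...)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort_validation(sprintf("'%s' must be a single non-negative number, got %s",
                             name, deparse(x)))
  }
  invisible(x)
}

check_pos <- function(x, name) {
  check_nonneg(x, name)
  if (x <= 0) {
    abort_validation(sprintf("'%s' must be strictly positive, got %g", name, x))
  }
  invisible(x)
}
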