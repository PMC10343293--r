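#' @keywords internal
"_PACKAGE"

# Shared argument checks. Errors are classed so callers/tests can condition
# on failure mode rather than message text.

abort <- function(msg, class) {
  stop(structure(class = c(class, "pkunmr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name),
          "invalid_parameter")
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    abort(sprintf("`%s` = %g is out of range", name, x), "invalid_parameter")
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x))
    abort(sprintf("`%s` must be an integer count", name), "invalid_parameter")
  invisible(as.integer(x))
}

# Derive a stream of child seeds from one master seed without consuming the
# global RNG state ordering (keeps nested simulations reproducible).
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
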