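# internal helpers

# Run `expr` under a reproducible RNG state when `seed` is given, without
# disturbing the caller's RNG stream. With seed = NULL the global stream is
# used (and advanced).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (allow_equal_lower) "[" else "(", format(lower),
      format(upper), if (allow_equal_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number.", name))
  invisible(as.integer(x))
}

# 2.5/50/97.5% quantiles of a vector, type 7
q95 <- function(x) {
  stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
}
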