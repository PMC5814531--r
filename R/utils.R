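#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seeds: one user-facing integer seed drives every
# stage, with per-stage/per-replicate offsets so stages can be re-run in any
# order without perturbing each other's draws. Kept below 2^31 - 1.
derive_seed <- function(seed, stage, rep = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + h * 7919 + rep * 104729) %% 2147483647L)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a finite numeric scalar", name))
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid(sprintf("'%s' = %g is outside the allowed range %s%g, %g%s",
                         name, x,
                         if (open_lower) "(" else "[", lower, upper,
                         if (open_upper) ")" else "]"))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || any(x < min) || any(x != round(x)))
    stop_invalid(sprintf("'%s' must be integer-valued and >= %d", name, min))
  invisible(as.integer(x))
}
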