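# Internal helpers shared across modules.

# Deterministic per-stage seed derived from a single pipeline seed, so each
# stage is reproducible in isolation. Knuth-style multiplicative mix of the
# seed with a string hash of the stage name, kept inside .Machine$integer.max.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483563 + 1)
}

# Round half away from zero (the convention used by the source tables),
# as opposed to base R's round-half-to-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    abort(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be an integer", name))
  invisible(as.integer(x))
}
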