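# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched, so every generator is a pure function of its spec.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "protoelec_invalid_spec")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative finite number.", name),
          class = "protoelec_invalid_spec")
  }
  invisible(x)
}

# Sampling interval of a uniformly sampled trace tibble (column `time_s`).
trace_dt <- function(trace) {
  t <- trace$time_s
  if (is.null(t) || length(t) < 2) {
    abort("trace must have a `time_s` column with at least two samples.",
          class = "protoelec_format_error")
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6 * max(abs(dt[1]), 1e-12)) {
    abort("trace time base is not uniform.", class = "protoelec_format_error")
  }
  dt[1]
}

# Channel columns of a multichannel trace (everything except time_s).
trace_channels <- function(trace) setdiff(names(trace), "time_s")

linear_detrend <- function(x) {
  n <- length(x)
  i <- seq_len(n)
  stats::lm.fit(cbind(1, i), x)$residuals
}
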