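# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a deterministic child seed for a named generator substream, so that a
# single root seed drives independent streams (behavior, EEG, LFP, EMG, ...)
# without lockstep correlation. Kept inside 32-bit integer range.
child_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483629)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what = "behavior table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s lacks required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

ms_to_samples <- function(ms, srate) {
  as.integer(round(ms * srate / 1000))
}

# Cohen's d for a paired contrast.
cohens_d_paired <- function(diffs) {
  mean(diffs) / sd(diffs)
}
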