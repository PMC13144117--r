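# Internal helpers shared across modules.

# Derive a child seed from a parent seed and a stage/iteration index.
# A single multiplicative-congruential step keeps all derived seeds inside
# the 32-bit integer range while decorrelating nearby indices.
derive_seed <- function(seed, index) {
  v <- (abs(as.numeric(seed)) * 48271 + as.numeric(index) * 16807 + 1) %%
    2147483647
  as.integer(v) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf("`%s` must be a single probability in [0, 1], got %s",
                 name, format(x)), call. = FALSE)
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d, got %s",
                 name, min, format(x)), call. = FALSE)
  }
  as.integer(x)
}

# C-locale sort so representative choices and output order do not depend on
# the session locale.
sort_c <- function(x) sort(x, method = "radix")
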