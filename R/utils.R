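# Internal helpers shared across modules.

# Derive a child seed from a master seed and a stage index. Kept below 2^31 so
# the result is always a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103515245 * k) %% 2147483647L)
}

# Evaluate `expr` under a local, seeded RNG without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr, .rng_kind = "Mersenne-Twister")
}

# Uniform integer draw on [lo, hi] (inclusive) using runif so draws stay on the
# generator stream.
runif_int <- function(n, lo, hi) {
  lo + floor(runif(n) * (hi - lo + 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}
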