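# Deterministic per-unit RNG streams.
#
# Every stochastic routine derives one substream seed per logical unit
# (e.g. per group x participant x odor trial, or per permutation repetition)
# from the caller's master seed by counter-based integer mixing. Datasets and
# null distributions are therefore invariant under reordering of the
# generation loops, and two runs with the same seed are bit-identical.

# Modulus is a prime below 2^31; the multiplier keeps every intermediate
# product below 2^53 so the arithmetic is exact in doubles.
.MIX_MOD <- 2147483629
.MIX_MULT <- 1000003

# Stable integer hash of a label, so RNG substreams attach to group/odor
# identity rather than to loop or configuration order.
.label_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 257 + ch) %% .MIX_MOD
  h
}

.stream_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% .MIX_MOD
  for (x in idx) {
    h <- (h * .MIX_MULT + as.numeric(x) + 1) %% .MIX_MOD
  }
  as.integer(h)
}

# Run `expr` under a derived stream without touching the caller's RNG state.
.with_stream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(.stream_seed(seed, ...))
  expr
}
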