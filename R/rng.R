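# Deterministic child-seed derivation so that the two modalities of a block
# (and the blocks of a cohort) draw from distinct, reproducible substreams.
# Lehmer-style mixing keeps every intermediate below 2^53, so arithmetic is
# exact in doubles, and the result stays inside R's 32-bit integer range.
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  m <- 2147483647 # 2^31 - 1
  state <- 1
  for (k in ks) {
    state <- (state * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(state)
}

# Evaluate `code` under a fixed seed when one is supplied, without touching
# the caller's RNG state; with seed = NULL the current stream is used.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
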