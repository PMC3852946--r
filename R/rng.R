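# RNG plumbing: private seeded scopes (so memoised simulations do not disturb
# replicate streams) and deterministic seed derivation.

# Evaluate `code` with an optional private seed, restoring the caller's RNG
# state afterwards when a seed was supplied.
with_rng_scope <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# Deterministic 31-bit seed from a key (a small string hash; stable across
# sessions and platforms).
key_seed <- function(...) {
  s <- paste(..., collapse = "_", sep = "_")
  h <- 17
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483629
  as.integer(h + 1)
}

# Distinct replicate seeds derived from a master seed.
spawn_seeds <- function(master_seed, n) {
  with_rng_scope(master_seed, sample.int(2147483646L, n))
}
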