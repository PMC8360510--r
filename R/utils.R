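# Small shared utilities.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage- or draw-specific seed from a base seed, staying inside the
# 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483647)
}
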