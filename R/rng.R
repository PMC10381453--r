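# Hierarchical seeding: study -> joint -> sample -> replicate.
#
# Every random draw in the generator runs under a sub-seed derived from the
# study seed and the indices of the unit being generated, so the draws for
# one sample never depend on how many other samples exist or in which order
# they are generated. All arithmetic stays below 2^53 so the hash is exact
# in double precision on any platform.

# Lehmer-style mix of an integer key sequence into a seed in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647  # 2^31 - 1
  h <- 1
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
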