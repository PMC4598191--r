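# Run expr under a temporary RNG state so generators are pure functions of
# their seed and never perturb the caller's stream.
local_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Named sub-seeds derived from one user seed: stream separation so adding a
# generator never changes another generator's draws. Kept below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(
    genome = 11L, segments = 23L, genotypes = 37L, events = 53L,
    frequencies = 71L, star = 89L, annotation = 101L, noise = 131L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 2654435 + off * 97) %% 2147483647)
}
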