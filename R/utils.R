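## Shared internal helpers.

## Seeded RNG scope: set the seed for a deterministic block and restore
## the caller's generator state on exit, so seeded package functions
## never perturb user-level randomness.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

## derive a bounded child seed from a base seed and a stream label
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + stream * 7919L) %% 2147483647L
}
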