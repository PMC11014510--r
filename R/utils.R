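## Seeded RNG streams that do not disturb the caller's global RNG state.
## Every stochastic entry point takes a `seed` and draws from its own
## stream, so results are bit-reproducible and composable.

make_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    get(".Random.seed", globalenv())
  })
  e
}

with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval(expr, envir = parent.frame())
}

sample_int <- function(rng, n, k, replace = FALSE) {
  with_rng(rng, sample.int(n, k, replace = replace))
}

runif_rng <- function(rng, n, min = 0, max = 1) {
  with_rng(rng, stats::runif(n, min, max))
}

derive_seed <- function(rng) sample_int(rng, .Machine$integer.max - 1L, 1L)
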