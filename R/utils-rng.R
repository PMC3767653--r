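# Isolated RNG streams. Simulation and cross-validation draw from their
# own seeded Mersenne-Twister states so results are pure functions of
# their configs and the caller's .Random.seed is never disturbed.

.localRng <- function(seed) {
  env <- new.env()
  swapIn <- function(state) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    old
  }
  swapOut <- function(old) {
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  local({
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    swapOut(old)
  })
  # evaluate a closure under this stream's state
  function(fn) {
    old <- swapIn(env$state)
    on.exit(swapOut(old))
    fn()
  }
}

# permutation sampler used for fold shuffles and site subsampling
.seededRng <- function(seed) {
  draw <- .localRng(seed)
  list(sample = function(n) draw(function() sample.int(n)),
       sampleRep = function(n, k)
         draw(function() sample.int(n, k, replace = TRUE)),
       norm = function(n) draw(function() stats::rnorm(n)))
}
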