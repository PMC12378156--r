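#' Derive a stream seed from a master seed
#'
#' All randomness in the package flows from one integer master seed. Each
#' stochastic stage (scene fields, footprint noise, plot noise, model fits,
#' optimizer) draws from its own stream, derived deterministically so that a
#' stage can be re-run in isolation and still reproduce the pipeline run.
#' The scheme is `(seed * 7919 + 104729 * stream) mod (2^31 - 1)`; both
#' multipliers are primes, and the result stays inside R's 32-bit integer
#' range.
#'
#' @param seed integer master seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return an integer seed suitable for [set.seed()].
#' @export
split_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) * 7919 + 104729 * (as.numeric(stream) + 1)
  as.integer(s %% m)
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(split_seed(seed, stream))
  force(code)
}
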