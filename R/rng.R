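#' Derive a reproducible sub-stream seed from the master seed
#'
#' All stochastic components (initialization, tie-breaks, action sampling,
#' the genetic search) are seeded from streams derived deterministically from
#' the single master seed, so that a run is reproducible from its resolved
#' config alone. The derivation is a small multiplicative hash of the purpose
#' label, kept strictly below 2^31 so it is always a valid integer seed.
#'
#' @param seed integer master seed.
#' @param purpose character label of the consuming component.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  h <- 0
  for (k in utf8ToInt(purpose)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, purpose, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, purpose))
  expr
}
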