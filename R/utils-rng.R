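#' Derive a reproducible substream seed
#'
#' Maps a master seed and a stream counter to a new seed via a fixed
#' linear-congruential step, so that per-subsample (or per-stage) random
#' streams are decoupled from one another and from iteration order.
#' The same (seed, stream) pair always yields the same substream seed,
#' which is what makes serial and resumed runs byte-identical.
#'
#' @param seed master integer seed.
#' @param stream non-negative integer counter (e.g. subsample index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime used by the classic Lehmer LCG
  s <- (abs(seed) %% m)
  s <- (s * 48271 + 1) %% m
  s <- (s + stream * 2654435761) %% m
  as.integer((s * 48271 + stream + 1) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
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

`%||%` <- function(a, b) if (is.null(a)) b else a
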