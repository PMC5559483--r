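# Deterministic seed derivation and scoped RNG use.
#
# All stochastic operations in the package consume seeds derived from a single
# master seed through mix_seed(), a small multiplicative-congruential hash.
# Child streams for (epoch, trajectory) pairs and for per-epoch spawning are
# labelled with distinct integer tags so adaptive and independent arms consume
# comparable streams at matched master seeds.

MOD31 <- 2147483647

#' Derive a child seed from a master seed and integer tags
#'
#' Deterministic counter-based split of a master seed: each distinct sequence
#' of non-negative integer tags yields a reproducible child seed in
#' `[1, 2^31 - 2]`. Used to give every (epoch, trajectory) pair and every
#' spawning decision its own random stream.
#'
#' @param seed Master seed (integer).
#' @param ... Non-negative integer tags identifying the stream.
#' @return An integer seed.
#' @export
mix_seed <- function(seed, ...) {
  s <- as.double(seed) %% MOD31
  for (k in c(...)) {
    # 69069 * (2^31 - 1) < 2^53: exact in double arithmetic
    s <- (s * 69069 + as.double(k) + 1) %% MOD31
  }
  as.integer(s %% (MOD31 - 2) + 1)
}

# Evaluate code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
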