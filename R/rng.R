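# Seeded substreams: all randomness in the package flows from one integer
# seed; per-unit substreams (per OTU, per stage) are derived by hashing the
# stream label into [1, 2^31 - 2] and mixing with the master seed.

substream_seed <- function(seed, id) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 31 + ch) %% m
  }
  s <- (abs(as.numeric(seed)) %% m)
  v <- (s * 48271 + h * 69621 + 1) %% m
  as.integer(v %% (m - 1) + 1)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_substream <- function(seed, id, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, id))
  expr
}
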