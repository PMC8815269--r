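# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a sub-seed; keeps results independent of evaluation order while
# staying within 32-bit integer range.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

stopIfNot1 <- function(x, what) {
  if (length(x) != 1L || is.na(x))
    stop(what, " must be a single non-missing value", call. = FALSE)
  x
}

# Empirical two-sided p-value with the +1 correction: always in (0, 1].
empiricalP <- function(es, nullEs) {
  (1 + sum(abs(nullEs) >= abs(es))) / (length(nullEs) + 1)
}

# Competition-free dense ranking used everywhere a deterministic permutation
# is needed: order by `primary` (ascending), ties by `id` (ascending).
permutationRank <- function(primary, id) {
  ord <- order(primary, id)
  r <- integer(length(primary))
  r[ord] <- seq_along(ord)
  r
}
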