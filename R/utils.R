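# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# add-one empirical p-value: never exactly zero
addOneP <- function(exceed, n) (1 + exceed) / (1 + n)

newPermutationResult <- function(statistic, observed, nullDraws, seed) {
  n <- length(nullDraws)
  new("PermutationResult", statistic = statistic, observed = observed,
      nullDraws = as.numeric(nullDraws),
      pValue = addOneP(sum(nullDraws >= observed), n),
      nReps = n, seed = as.integer(seed))
}
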