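# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (expr still consumes it).
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

# Derive independent sub-seeds from a master seed, all below 2^31.
deriveSeeds <- function(seed, n) {
  if (is.null(seed) || is.na(seed))
    return(rep(NA_integer_, n))
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

newEstimate <- function(kHat, method, diagnostics = list()) {
  new("ClusterCountEstimate", kHat = as.integer(kHat), method = method,
      diagnostics = diagnostics)
}
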