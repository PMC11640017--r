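#' Derive a child seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer offsets
#' (fold index, configuration index, stage id, ...) so that every source of
#' randomness in an experiment draws from its own stream while remaining
#' fully reproducible from the single master seed. The result is always a
#' positive integer below 2^31.
#'
#' @param seed integer master seed.
#' @param ... integer offsets identifying the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  h <- as.double(seed) %% 2147483647
  for (o in offs) {
    # LCG-style mixing; constants from Numerical Recipes, modulus 2^31 - 1
    h <- (h * 1103515245 + 12345 + as.double(o) * 2654435769) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
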