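# Internal helpers shared across modules.

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed, kept inside the 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

clipToBitDepth <- function(x, bitDepth) {
  mx <- 2^bitDepth - 1
  clipped <- any(x > mx) || any(x < 0)
  x[x > mx] <- mx
  x[x < 0] <- 0
  list(values = x, clipped = clipped)
}

# The four-parameter logistic on the log10 dose axis.
fourPL <- function(doseMm, bottom, top, logEc50, hill) {
  bottom + (top - bottom) / (1 + 10^((logEc50 - log10(doseMm)) * hill))
}
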