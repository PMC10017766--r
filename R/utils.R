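# internal helpers shared across modules

# Evaluate expr with a local RNG state: the caller's .Random.seed is saved and
# restored, so generators are pure functions of (parameters, seed) and never
# disturb global random state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# single Gaussian bump, used by generator and fitter alike
gaussBump <- function(x, A, mu, sigma) A * exp(-(x - mu)^2 / (2 * sigma^2))
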