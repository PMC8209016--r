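# internal helpers

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. Every generator routes its randomness through this, which
# is what makes each one a pure function of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("`seed` must be a single finite integer")
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# standard error of the mean with the n-1 sample standard deviation
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
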