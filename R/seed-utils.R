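# RNG discipline: every stochastic entry point takes an integer seed and leaves
# the caller's .Random.seed untouched.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seeds for (subject, run, ...) streams, kept inside the
# 32-bit signed range set.seed() accepts.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
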