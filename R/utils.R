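# Internal helpers shared across modules.

# Deterministic integer seed stream: folds any number of integer components
# into [1, 2^31 - 2] with a multiplicative-congruential mix. Doubles are exact
# below 2^53 so the modular arithmetic is safe.
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (v in parts) {
    s <- (s * 69069 + (as.numeric(v) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(s + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s", name, deparse(x)))
  }
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be in [%s, %s]", name, lo, hi))
  }
}
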