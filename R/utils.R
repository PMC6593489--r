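# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a local RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. All user-facing randomness goes through
## this so that a master seed makes a whole run reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a child seed from a master seed and a stream index, kept within
## the 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0
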