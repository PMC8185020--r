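# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that a given (seed, params) pair is reproducible and
# never disturbs user RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying within the
# 32-bit signed integer range expected by set.seed().
child_seed <- function(seed, i) {
  (as.double(seed) * 1009 + as.double(i) * 9973) %% 2147483647
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
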