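#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded generators never perturb user
#' code that happens to draw random numbers afterwards.
#'
#' @param seed Integer seed (scalar, < 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, kept inside the
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483629
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}
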