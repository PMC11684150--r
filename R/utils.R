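## weeks per month used whenever results are reported on a monthly grid
WEEKS_PER_MONTH <- 52 / 12

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the session's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## stable child seeds for pipeline stages: distinct, < 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) * 48271 + k * 1013) %% 2147480009L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
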