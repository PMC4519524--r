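# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's random stream. With `seed = NULL` the expression
#' runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed from a parent seed
#'
#' Deterministic stream splitting: a Lehmer step on the parent seed mixed
#' with the child index, kept strictly below 2^31 so the result is always a
#' valid R integer seed.
#'
#' @param seed parent integer seed.
#' @param index nonnegative integer distinguishing the child stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.numeric(seed)) %% m)
  for (k in c(as.numeric(index) + 1, 7919)) {
    x <- (x * 48271 + k) %% m
  }
  as.integer(x)
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
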