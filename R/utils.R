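# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's RNG stream. `seed = NULL` leaves the stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Check that a numeric vector holds non-negative integers (possibly stored
#' as doubles).
#' @noRd
is_count_vector <- function(y) {
  is.numeric(y) && all(is.finite(y)) && all(y >= 0) && all(y == floor(y))
}

#' @noRd
log_msg <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}
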