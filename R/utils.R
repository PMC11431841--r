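# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#'
#' All exported stochastic operations funnel randomness through this helper so
#' a user-supplied seed is honoured without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a module-prefixed message
#' @noRd
fail <- function(...) stop(sprintf(...), call. = FALSE)

#' Informational logging to stderr; suppressible via suppressMessages()
#' @noRd
log_info <- function(...) message(sprintf(...))
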