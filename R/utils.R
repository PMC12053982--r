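#' Run code with a fixed, restored RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` with the Mersenne-Twister /
#' Inversion generators pinned (so schedules and simulations are reproducible
#' across R sessions), then restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
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
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Message displayed when a block or session is complete
#' @format character scalar.
#' @export
SESSION_END_MESSAGE <- "This is the end of the session"
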