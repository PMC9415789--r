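# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' All stochastic operations in the package funnel their seed through this
#' helper so that a given seed always yields the same stream (Mersenne-Twister,
#' R's default) and the caller's RNG state is left untouched.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# stop() with a classed condition so callers (and the CLI) can map error
# families to exit codes.
abort_acry <- function(msg, class) {
  stop(structure(class = c(class, "acrytrend_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_absent <- function(x) is.na(x)
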