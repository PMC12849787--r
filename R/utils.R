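#' Evaluate an expression under a private RNG stream
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so package-internal randomness never disturbs the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stop() with a classed condition so callers can distinguish error families
gf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gatformer_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == as.integer(x)

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
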