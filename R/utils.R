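# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's random
#' stream afterwards.  All stochastic operations in the package route
#' through this, so results are pure functions of (inputs, seed).
#'
#' @param seed integer seed (NULL leaves the stream untouched).
#' @param code expression to evaluate.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a stage-specific seed from a root seed
#'
#' Keeps every pipeline stage's random stream independent while remaining a
#' deterministic function of the root seed; the result stays inside R's
#' 32-bit signed integer range.
#'
#' @param seed root integer seed.
#' @param stage stage label.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L) + 1L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# square metres per acre (international acre)
ACRE_M2 <- 4046.8564224
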