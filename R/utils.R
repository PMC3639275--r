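#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random-number stream.
#'
#' @param seed integer seed, or NULL to leave the RNG stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic child seed
#'
#' One master seed drives a whole simulated experiment; per-subject and
#' per-run streams get distinct, reproducible child seeds. The derivation is
#' a fixed linear-congruential hash of the master seed and the index path,
#' kept strictly below 2^31.
#'
#' @param master integer master seed.
#' @param ... integer indices (e.g. subject, run, stream id).
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (v in idx) h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  as.integer(h + 1)
}

# consistent ms -> s conversion; the single point where RT changes units
ms_to_s <- function(ms) ms / 1000

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
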