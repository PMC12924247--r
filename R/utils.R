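`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals
#' never perturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# An isolated, resumable RNG stream: used by the tissue environment and the
# agents so that episodes are bit-reproducible given (seed, action sequence)
# regardless of what the caller does with the global RNG.
rng_stream <- function(seed) {
  state <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  list(state = state)
}

rng_draw <- function(stream, expr_fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  value <- expr_fn()
  stream$state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  list(value = value, stream = stream)
}

# Derive a bounded per-module seed from one global seed, so that one CLI /
# script seed fans out to independent module streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483562) + 1L
}

vec_norm <- function(v) sqrt(sum(v * v))
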