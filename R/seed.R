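#' Evaluate an expression under a local, reproducible RNG state
#'
#' All stochastic generators in this package take a mandatory `seed`
#' argument and never touch the caller's global RNG stream: the previous
#' `.Random.seed` is restored on exit.  The RNG kind is pinned
#' (Mersenne-Twister / Inversion / Rejection) so identical seeds give
#' bit-identical draws across R versions.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Derive a distinct child seed for a named substream from a base seed.
# Keeps all randomness flowing from one config seed while stages stay
# decoupled.  Result is always a valid 32-bit integer seed.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
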