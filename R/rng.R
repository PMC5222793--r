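# Named, independent RNG substreams.
#
# Each simulated session draws from two independent streams -- one for the
# sampler (tie-breaks, interleaving schedules, top-10% draws) and one for the
# observer's Bernoulli responses -- so that switching samplers never perturbs
# the observer's random draws at a matched seed.

#' Create an independent random-number stream
#'
#' @param seed Integer seed for the stream.
#' @return An environment holding the stream's `.Random.seed` state.
#' @keywords internal
#' @export
new_rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression using a given RNG stream
#'
#' Swaps the stream's state into the global RNG, evaluates `expr`, saves the
#' advanced state back into the stream, and restores the previous global RNG
#' state.
#'
#' @param stream A [new_rng_stream()] object.
#' @param expr Expression to evaluate.
#' @keywords internal
#' @export
with_rng <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' A small deterministic integer hash (multiplicative, modulo a Mersenne
#' prime) mapping `(seed, label, ...)` to a seed in `[1, 2^31 - 2]`, used to
#' give every run/stream its own reproducible seed.
#'
#' @param seed Integer base seed.
#' @param ... Additional labels (character or integer-like) mixed into the
#'   hash.
#' @return A single integer seed.
#' @keywords internal
#' @export
derive_seed <- function(seed, ...) {
  p <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% p
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(part)))) {
      h <- (h * 31 + ch) %% p
    }
  }
  as.integer(h %% (p - 1) + 1)
}
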