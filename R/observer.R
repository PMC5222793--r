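# Simulated 2AFC observers: Bernoulli responses drawn from the 2-D
# psychometric function, with an independent named RNG stream so that
# sampler-side randomness never perturbs the observer's draws.

#' Reference observer parameter sets
#'
#' Two standard simulated observers: `"normal"` (a typical normal-vision
#' CSF, peak sensitivity near 3.2 c/d) and `"amblyope"` (reduced amplitude
#' with the peak shifted to higher frequency, 7.2 c/d), both with logistic
#' slope 4 and lapse rate 0.02 in a 2AFC task (guess rate 1/2).
#'
#' @param name `"normal"` or `"amblyope"`.
#' @return An [observer_params()] object.
#' @examples
#' observer_preset("normal")    # M = 100, A = 0.8, F = 4
#' observer_preset("amblyope")  # M = 40,  A = 1.2, F = 6
#' @export
observer_preset <- function(name = c("normal", "amblyope")) {
  name <- match.arg(name)
  switch(name,
    normal   = observer_params(M = 100, A = 0.8, F = 4, beta = 4,
                               gamma = 0.5, delta = 0.02),
    amblyope = observer_params(M = 40, A = 1.2, F = 6, beta = 4,
                               gamma = 0.5, delta = 0.02))
}

#' Create a simulated Bernoulli observer
#'
#' @param params An [observer_params()] object (or a preset name accepted by
#'   [observer_preset()]).
#' @param seed Integer seed for the observer's private response stream.
#' @return An object of class `sim_observer` with a `respond(sf, contrast)`
#'   function drawing a binary response.
#' @examples
#' obs <- simulated_observer("normal", seed = 1)
#' obs$respond(4, 0.01)
#' @export
simulated_observer <- function(params = "normal", seed = 1L) {
  if (is.character(params)) params <- observer_preset(params)
  stopifnot(inherits(params, "csf_params"))
  stream <- new_rng_stream(seed)
  obj <- new.env(parent = emptyenv())
  obj$params <- params
  obj$respond <- function(sf, contrast) {
    p <- detect_prob(sf, contrast, params)
    with_rng(stream, as.integer(stats::runif(length(p)) < p))
  }
  class(obj) <- "sim_observer"
  obj
}

#' @export
print.sim_observer <- function(x, ...) {
  cat("Simulated 2AFC observer\n")
  print(x$params)
  invisible(x)
}
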