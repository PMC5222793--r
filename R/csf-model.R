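#' Logistic psychometric function of log contrast
#'
#' Probability of a positive ("detected") response at Michelson contrast `c`
#' for a logistic psychometric function parameterized by its midpoint
#' (threshold) `alpha`, slope `beta`, guess rate `gamma` and lapse rate
#' `delta`:
#' \deqn{P = \gamma + \frac{1-\gamma-\delta}{1 + e^{-\beta(\ln c - \ln\alpha)}}}
#'
#' The function is strictly increasing in `contrast` (for `beta > 0`) and
#' bounded in `(gamma, 1 - delta)`.
#'
#' @param contrast Michelson contrast, strictly positive. Vectorized.
#' @param alpha Threshold contrast (the midpoint), strictly positive.
#' @param beta Slope of the logistic in log-contrast units, strictly positive.
#' @param gamma Guess rate (lower asymptote); 1/2 for a 2AFC task.
#' @param delta Lapse rate (1 minus the upper asymptote).
#' @return Probability of a positive response, same length as the longest
#'   vector input.
#' @examples
#' logistic_p(0.01, alpha = 0.01, beta = 4)   # midpoint: 0.74 at delta = 0.02
#' @export
logistic_p <- function(contrast, alpha, beta, gamma = 0.5, delta = 0.02) {
  if (any(contrast <= 0)) stop("`contrast` must be strictly positive")
  if (any(alpha <= 0)) stop("`alpha` must be strictly positive")
  if (any(beta <= 0)) stop("`beta` must be strictly positive")
  if (any(gamma < 0) || any(gamma >= 1) || any(delta < 0) || any(delta >= 1) ||
      any(gamma + delta >= 1)) {
    stop("require 0 <= gamma, delta and gamma + delta < 1")
  }
  gamma + (1 - gamma - delta) * stats::plogis(beta * (log(contrast) - log(alpha)))
}

#' Double-exponential contrast sensitivity function
#'
#' Sensitivity (reciprocal threshold contrast) at spatial frequency `sf`:
#' \deqn{S(f) = M f^{A} e^{-f/F}}
#' `S` is unimodal in `f`, peaking at `f = A F` with amplitude
#' `M (F A)^A exp(-A)`.
#'
#' @param sf Spatial frequency in cycles/degree, strictly positive. Vectorized.
#' @param M Overall sensitivity scale, > 0.
#' @param A Low-frequency rise exponent, > 0.
#' @param F High-frequency exponential decay constant (c/d), > 0.
#' @return Sensitivity (1 / threshold contrast).
#' @examples
#' csf_sensitivity(3.2, M = 100, A = 0.8, F = 4)  # at the peak frequency
#' @export
csf_sensitivity <- function(sf, M, A, F) {
  if (any(sf <= 0)) stop("`sf` must be strictly positive")
  if (any(M <= 0) || any(A <= 0) || any(F <= 0)) {
    stop("`M`, `A` and `F` must be strictly positive")
  }
  M * sf^A * exp(-sf / F)
}

#' Observer parameter vector
#'
#' Bundles the six parameters of the 2-D psychometric model: the CSF shape
#' parameters `M`, `A`, `F`, the logistic slope `beta`, the guess rate
#' `gamma` (fixed by the task design, 1/2 for 2AFC) and the lapse rate
#' `delta`.
#'
#' @param M,A,F CSF shape parameters, strictly positive (see
#'   [csf_sensitivity()]).
#' @param beta Logistic slope, strictly positive.
#' @param gamma Guess rate in `[0, 1)`; defaults to 1/2 (2AFC).
#' @param delta Lapse rate in `[0, 1)`; `gamma + delta` must be < 1.
#' @return An object of class `csf_params` (a named list).
#' @examples
#' observer_params(M = 100, A = 0.8, F = 4, beta = 4)
#' @export
observer_params <- function(M, A, F, beta, gamma = 0.5, delta = 0.02) {
  stopifnot(M > 0, A > 0, F > 0, beta > 0,
            gamma >= 0, gamma < 1, delta >= 0, delta < 1, gamma + delta < 1)
  structure(list(M = M, A = A, F = F, beta = beta, gamma = gamma,
                 delta = delta),
            class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(
    "CSF observer: M = %g, A = %g, F = %g (peak %.3g c/d), beta = %g, gamma = %g, delta = %g\n",
    x$M, x$A, x$F, x$A * x$F, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' Detection probability on the 2-D frequency-contrast plane
#'
#' The 2-D psychometric function: the CSF threshold `1/S(f)` is the midpoint
#' of the logistic along log contrast, so
#' \deqn{P = \gamma + \frac{1-\gamma-\delta}
#'   {1 + e^{-\beta(\ln c + \ln M + A \ln f - f/F)}}}
#' identical to `logistic_p(c, 1 / csf_sensitivity(f, M, A, F), beta, ...)`.
#'
#' @param sf Spatial frequency (c/d), > 0. Vectorized together with `contrast`.
#' @param contrast Michelson contrast, > 0.
#' @param theta A [observer_params()] object (or any list with elements
#'   `M`, `A`, `F`, `beta`, `gamma`, `delta`).
#' @return Probability of a positive response.
#' @examples
#' th <- observer_params(100, 0.8, 4, 4)
#' detect_prob(3.2, 1 / csf_sensitivity(3.2, 100, 0.8, 4), th)  # 0.74
#' @export
detect_prob <- function(sf, contrast, theta) {
  if (any(sf <= 0)) stop("`sf` must be strictly positive")
  if (any(contrast <= 0)) stop("`contrast` must be strictly positive")
  z <- theta$beta * (log(contrast) + log(theta$M) + theta$A * log(sf) -
                       sf / theta$F)
  theta$gamma + (1 - theta$gamma - theta$delta) * stats::plogis(z)
}

#' Gradient of the detection probability in log10 parameter space
#'
#' Analytic partial derivatives of [detect_prob()] with respect to
#' `log10(M)`, `log10(A)`, `log10(F)` and `log10(beta)`, the coordinates in
#' which the parameter grid and priors live. These feed the Fisher
#' information matrix used by the D-optimal (information-gain) sampler; the
#' lapse rate is treated as a nuisance parameter and excluded.
#'
#' @inheritParams detect_prob
#' @return A matrix with one row per stimulus and columns
#'   `log10M`, `log10A`, `log10F`, `log10beta`.
#' @export
detect_prob_grad <- function(sf, contrast, theta) {
  if (any(sf <= 0)) stop("`sf` must be strictly positive")
  if (any(contrast <= 0)) stop("`contrast` must be strictly positive")
  n <- max(length(sf), length(contrast))
  sf <- rep_len(sf, n); contrast <- rep_len(contrast, n)
  z <- theta$beta * (log(contrast) + log(theta$M) + theta$A * log(sf) -
                       sf / theta$F)
  s <- stats::plogis(z)
  D <- (1 - theta$gamma - theta$delta) * s * (1 - s)  # dP/dz
  ln10 <- log(10)
  cbind(
    log10M    = D * theta$beta * ln10,
    log10A    = D * theta$beta * log(sf) * theta$A * ln10,
    log10F    = D * theta$beta * (sf / theta$F) * ln10,
    log10beta = D * z * ln10
  )
}

#' Stimulus grid of presentable spatial frequencies and contrasts
#'
#' The default grid spans 12 spatial frequencies from 0.5 to 22.6 c/d in
#' 0.5 log2 steps and 151 contrasts from 0.001 to 1 in 0.02 log10 steps.
#' All adaptive samplers propose stimuli on this grid.
#'
#' @param sfs Ordered vector of spatial frequencies (c/d).
#' @param contrasts Ordered vector of Michelson contrasts in (0, 1].
#' @return An object of class `stimulus_grid`.
#' @export
stimulus_grid <- function(sfs = 0.5 * 2^seq(0, 5.5, by = 0.5),
                          contrasts = 10^seq(-3, 0, by = 0.02)) {
  stopifnot(all(sfs > 0), all(contrasts > 0), all(contrasts <= 1),
            !is.unsorted(sfs), !is.unsorted(contrasts))
  structure(list(sfs = sfs, contrasts = contrasts), class = "stimulus_grid")
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf("Stimulus grid: %d spatial frequencies (%.3g-%.3g c/d) x %d contrasts (%g-%g)\n",
              length(x$sfs), min(x$sfs), max(x$sfs),
              length(x$contrasts), min(x$contrasts), max(x$contrasts)))
  invisible(x)
}

#' Snap a contrast to the nearest grid node
#'
#' Snapping happens in log10-contrast space; exact midpoints between two
#' nodes resolve toward the lower contrast. Values outside the grid range
#' are clamped to the endpoints.
#'
#' @param contrast Contrast value(s) to snap.
#' @param grid A [stimulus_grid()].
#' @return Contrast value(s) taken from `grid$contrasts`.
#' @export
snap_contrast <- function(contrast, grid = stimulus_grid()) {
  lc <- log10(pmin(pmax(contrast, min(grid$contrasts)), max(grid$contrasts)))
  nodes <- log10(grid$contrasts)
  idx <- findInterval(lc, nodes, all.inside = TRUE)
  d_lo <- lc - nodes[idx]
  d_hi <- nodes[idx + 1] - lc
  # ties (equidistant) go to the lower node
  pick_hi <- d_hi < d_lo - 1e-12
  grid$contrasts[idx + as.integer(pick_hi)]
}
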