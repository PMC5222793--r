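# Gridded 5-D Bayesian engine over (M, A, F, beta, delta) in log10 space.
#
# The posterior lives on a separable rectangular grid; the likelihood of a
# trial (f, c, r) at a node is P^r (1-P)^(1-r) with P the 2-D psychometric
# function evaluated at the node's (linear-scale) parameters. The guess rate
# gamma is a fixed task constant (1/2 for 2AFC), not a grid dimension.

DIM_NAMES <- c("M", "A", "F", "beta", "delta")

#' Discretized parameter grid for 5-D Bayesian CSF inference
#'
#' Builds the rectangular log10-space grid over (M, A, F, beta, delta) on
#' which the prior and posterior are represented. Each axis is linearly
#' spaced in log10 units and spans the prior mean plus/minus `span_sd` prior
#' standard deviations (endpoints included).
#'
#' @param sizes Integer vector of node counts per dimension; default
#'   `c(32, 32, 32, 8, 8)`.
#' @param prior_mean Prior mean per dimension in log10 units. The default
#'   centers the CSF parameters on a typical normal-vision observer and puts
#'   a narrow prior on the nuisance lapse rate (`log10 delta = -1.70`,
#'   i.e. delta of about 0.02).
#' @param prior_diag Prior dispersion per dimension; interpreted as
#'   standard deviations by default (`diag_is_sd = TRUE`), the reading under
#'   which the engine reproduces its reference precision benchmarks.
#' @param diag_is_sd If `FALSE`, `prior_diag` holds variances instead of
#'   standard deviations.
#' @param span_sd Half-width of each axis in prior standard deviations.
#' @param gamma Fixed guess rate of the task (1/2 for 2AFC).
#' @return An object of class `csf_param_grid`.
#' @examples
#' g <- csf_param_grid()
#' prod(g$sizes)  # about two million nodes
#' @export
csf_param_grid <- function(sizes = c(32L, 32L, 32L, 8L, 8L),
                           prior_mean = c(2.00, -0.30, 0.78, 0.62, -1.70),
                           prior_diag = c(0.50, 0.50, 0.50, 0.11, 0.02),
                           diag_is_sd = TRUE,
                           span_sd = 2.5,
                           gamma = 0.5) {
  stopifnot(length(sizes) == 5, length(prior_mean) == 5,
            length(prior_diag) == 5, all(sizes >= 2), all(prior_diag > 0),
            span_sd > 0, gamma >= 0, gamma < 1)
  sizes <- as.integer(sizes)
  prior_sd <- if (diag_is_sd) prior_diag else sqrt(prior_diag)
  axes <- lapply(seq_len(5), function(d) {
    seq(prior_mean[d] - span_sd * prior_sd[d],
        prior_mean[d] + span_sd * prior_sd[d], length.out = sizes[d])
  })
  names(axes) <- DIM_NAMES
  structure(list(axes = axes, sizes = sizes, prior_mean = prior_mean,
                 prior_sd = prior_sd, gamma = gamma),
            class = "csf_param_grid")
}

#' @export
print.csf_param_grid <- function(x, ...) {
  cat(sprintf("CSF parameter grid [%s] in log10(%s), gamma = %g\n",
              paste(x$sizes, collapse = ", "),
              paste(DIM_NAMES, collapse = ", "), x$gamma))
  for (d in seq_len(5)) {
    cat(sprintf("  log10 %-5s: %d nodes in [%.3f, %.3f]\n", DIM_NAMES[d],
                x$sizes[d], min(x$axes[[d]]), max(x$axes[[d]])))
  }
  invisible(x)
}

# ln(alpha) = -ln S(f) at every (M, A, F) grid combination, one column per
# spatial frequency. M varies fastest, then A, then F (R array order).
node_lnalpha <- function(grid, sfs) {
  lnM <- log(10) * grid$axes$M
  Av <- 10^grid$axes$A
  Fv <- 10^grid$axes$F
  out <- matrix(0, length(lnM) * length(Av) * length(Fv), length(sfs))
  for (i in seq_along(sfs)) {
    f <- sfs[i]
    t1 <- outer(-lnM, -Av * log(f), "+")          # [n1, n2]
    out[, i] <- as.vector(outer(as.vector(t1), f / Fv, "+"))
  }
  out
}

#' Build the prior posterior object on a parameter grid
#'
#' Evaluates the joint (diagonal-covariance) normal prior density at every
#' grid node in log10 space and renormalizes to total mass one. With
#' `prior = "uniform"` every node receives identical mass.
#'
#' @param grid A [csf_param_grid()].
#' @param prior Either `"normal"` (the grid's configured prior) or
#'   `"uniform"`.
#' @return An object of class `csf_posterior` with elements `grid` and
#'   `mass` (a 5-D array summing to one).
#' @export
build_prior <- function(grid, prior = c("normal", "uniform")) {
  prior <- match.arg(prior)
  key <- paste("prior", grid_signature(grid), prior)
  mass <- .csf_cache[[key]]
  if (is.null(mass)) {
    if (prior == "uniform") {
      mass <- array(1 / prod(grid$sizes), dim = grid$sizes)
    } else {
      w <- lapply(seq_len(5), function(d) {
        stats::dnorm(grid$axes[[d]], grid$prior_mean[d], grid$prior_sd[d])
      })
      mass <- Reduce(function(a, b) outer(a, b), w)
      mass <- mass / sum(mass)
      dim(mass) <- grid$sizes
    }
    .csf_cache[[key]] <- mass
  }
  structure(list(grid = grid, mass = mass), class = "csf_posterior")
}

#' @export
print.csf_posterior <- function(x, ...) {
  est <- point_estimate(x)
  cat(sprintf("CSF posterior on a [%s] grid; entropy %.3f nats\n",
              paste(x$grid$sizes, collapse = ", "), posterior_entropy(x)))
  cat("  marginal means (log10):",
      paste(sprintf("%s = %.3f", DIM_NAMES, est$log10), collapse = ", "), "\n")
  invisible(x)
}

# Detection probability at one stimulus for every grid node, returned as a
# matrix [nM*nA*nF*nbeta, ndelta].
node_detect_prob <- function(grid, sf, contrast, lnalpha_col = NULL) {
  if (is.null(lnalpha_col)) lnalpha_col <- node_lnalpha(grid, sf)[, 1]
  p <- as.vector(stats::plogis(outer(log(contrast) - lnalpha_col,
                                     10^grid$axes$beta)))
  deltas <- 10^grid$axes$delta
  g <- grid$gamma
  vapply(deltas, function(d) g + (1 - g - d) * p, numeric(length(p)))
}

#' Single-trial Bayesian update of a gridded posterior
#'
#' Multiplies the posterior mass at every node by the Bernoulli likelihood
#' `P^r (1-P)^(1-r)` of the observed response and renormalizes.
#'
#' @param post A `csf_posterior` (see [build_prior()]).
#' @param sf Spatial frequency of the trial (c/d).
#' @param contrast Michelson contrast of the trial.
#' @param response Binary response (1 = detected/correct, 0 = not).
#' @return The updated `csf_posterior`.
#' @export
update_posterior <- function(post, sf, contrast, response) {
  stopifnot(length(response) == 1, response %in% c(0, 1))
  grid <- post$grid
  P <- node_detect_prob(grid, sf, contrast)
  lik <- if (response == 1) P else 1 - P
  mass <- as.vector(post$mass) * as.vector(lik)
  tot <- sum(mass)
  if (!is.finite(tot) || tot <= 0) {
    stop("posterior update degenerated to zero total mass")
  }
  post$mass <- array(mass / tot, dim = grid$sizes)
  post
}

# Collapse a trial log into unique (sf, contrast) cells with counts of
# positive (n1) and negative (n0) responses. The likelihood factorizes over
# trials, so pooled counts are sufficient.
aggregate_trials <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("sf_cpd", "contrast", "response") %in% names(trials)))
  if (nrow(trials) == 0) {
    return(data.frame(sf_cpd = numeric(), contrast = numeric(),
                      n1 = numeric(), n0 = numeric()))
  }
  if (!all(trials$response %in% c(0, 1))) {
    stop("responses must be 0 or 1")
  }
  key <- paste(format(trials$sf_cpd, digits = 15),
               format(trials$contrast, digits = 15))
  idx <- !duplicated(key)
  cells <- trials[idx, c("sf_cpd", "contrast")]
  cells$n1 <- as.vector(rowsum(as.numeric(trials$response), key)[unique(key), ])
  nall <- as.vector(table(factor(key, levels = unique(key))))
  cells$n0 <- nall - cells$n1
  rownames(cells) <- NULL
  cells
}

# Exact pooled log-likelihood over all grid nodes, returned as a vector in
# the grid's array order.
exact_pooled_loglik <- function(grid, cells) {
  sfs <- unique(cells$sf_cpd)
  lnalpha <- node_lnalpha(grid, sfs)
  nmaf <- nrow(lnalpha)
  nb <- grid$sizes[4]; nd <- grid$sizes[5]
  betas <- 10^grid$axes$beta
  deltas <- 10^grid$axes$delta
  g <- grid$gamma
  ll <- matrix(0, nmaf * nb, nd)
  for (ci in seq_len(nrow(cells))) {
    a <- lnalpha[, match(cells$sf_cpd[ci], sfs)]
    t0 <- log(cells$contrast[ci]) - a
    p <- as.vector(stats::plogis(outer(t0, betas)))
    n1 <- cells$n1[ci]; n0 <- cells$n0[ci]
    for (m in seq_len(nd)) {
      P <- g + (1 - g - deltas[m]) * p
      if (n1 > 0) ll[, m] <- ll[, m] + n1 * log(P)
      if (n0 > 0) ll[, m] <- ll[, m] + n0 * log1p(-P)
    }
  }
  as.vector(ll)
}

# --- fast approximate pooled log-likelihood -------------------------------
#
# Two-stage tabulation: (1) per session, tabulate log P and log(1-P) on a
# dense 1-D axis of z0 = ln(c) - ln(alpha) for every (beta, delta) node;
# (2) per trial log, accumulate the per-frequency pooled log-likelihood on a
# dense ln(alpha) axis by linear interpolation into the z0 tables, then map
# it onto the grid's ln(alpha) values, again by linear interpolation. This
# turns the ~10^8 log() evaluations of the exact path into table lookups.

.csf_cache <- new.env(parent = emptyenv())

# log prior mass vector, cached per grid configuration
log_prior_vec <- function(grid, prior = "normal") {
  key <- paste("lprior", grid_signature(grid), prior)
  hit <- .csf_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- log(as.vector(build_prior(grid, prior)$mass))
  .csf_cache[[key]] <- out
  out
}

grid_signature <- function(grid) {
  paste(c(sprintf("%.12g", unlist(grid$axes)), sprintf("%.12g", grid$gamma)),
        collapse = ",")
}

loglik_tables <- function(grid, z0min, z0max, n_z = 32768L) {
  key <- paste(grid_signature(grid), sprintf("%.6g %.6g %d", z0min, z0max, n_z))
  hit <- .csf_cache[[key]]
  if (!is.null(hit)) return(hit)
  z0 <- seq(z0min, z0max, length.out = n_z)
  nb <- grid$sizes[4]; nd <- grid$sizes[5]
  betas <- 10^grid$axes$beta
  deltas <- 10^grid$axes$delta
  g <- grid$gamma
  T1 <- matrix(0, n_z, nb * nd)
  T0 <- matrix(0, n_z, nb * nd)
  for (k in seq_len(nb)) {
    p <- stats::plogis(betas[k] * z0)
    for (m in seq_len(nd)) {
      P <- g + (1 - g - deltas[m]) * p
      col <- (m - 1L) * nb + k
      T1[, col] <- log(P)
      T0[, col] <- log1p(-P)
    }
  }
  out <- list(z0 = z0, dz = z0[2] - z0[1], T1 = T1, T0 = T0)
  .csf_cache[[key]] <- out
  out
}

approx_pooled_loglik <- function(grid, cells, n_dense = 4096L) {
  sfs <- sort(unique(cells$sf_cpd))  # canonical order so the cache is shared
  akey <- paste("lnalpha", grid_signature(grid),
                paste(sprintf("%.10g", sfs), collapse = ","))
  lnalpha <- .csf_cache[[akey]]
  if (is.null(lnalpha)) {
    lnalpha <- node_lnalpha(grid, sfs)
    .csf_cache[[akey]] <- lnalpha
  }
  lnc <- log(cells$contrast)
  # round the table range outward to whole units (covering at least the
  # standard 0.001-1 contrast span) so different trial logs on the same
  # grid share one cached table
  z0min <- floor(min(lnc, log(1e-3)) - max(lnalpha) - 0.5)
  z0max <- ceiling(max(lnc, 0) - min(lnalpha) + 0.5)
  tab <- loglik_tables(grid, z0min, z0max)
  cpp_pooled_loglik(lnalpha, as.integer(match(cells$sf_cpd, sfs)),
                    lnc, cells$n1, cells$n0,
                    tab$T1, tab$T0, tab$z0[1], tab$dz,
                    grid$sizes[4] * grid$sizes[5], as.integer(n_dense))
}

#' Batch Bayesian inference from a trial log
#'
#' Builds the prior and folds the Bernoulli likelihood of every trial into
#' it. Because the likelihood factorizes over trials the result is
#' independent of trial order and identical (up to floating-point rounding)
#' to calling [update_posterior()] sequentially. Accumulation is done in log
#' space per node, so long logs with extreme nodes cannot underflow.
#'
#' @param trials Data frame with columns `sf_cpd`, `contrast`, `response`
#'   (binary); extra columns are ignored.
#' @param grid A [csf_param_grid()].
#' @param prior Prior passed to [build_prior()].
#' @param approx If `TRUE`, evaluate the pooled log-likelihood through the
#'   table-interpolation kernel (much faster, accurate to about 1e-4 in
#'   pooled log-likelihood); if `FALSE` (default), evaluate it exactly.
#' @return The final `csf_posterior`.
#' @examples
#' g <- csf_param_grid(sizes = c(12, 12, 12, 5, 5))
#' obs <- observer_preset("normal")
#' log1 <- data.frame(sf_cpd = 4, contrast = c(0.01, 0.02), response = c(0, 1))
#' infer_csf(log1, g)
#' @export
infer_csf <- function(trials, grid = csf_param_grid(),
                      prior = c("normal", "uniform"), approx = FALSE) {
  prior <- match.arg(prior)
  post <- build_prior(grid, prior)
  cells <- aggregate_trials(trials)
  if (nrow(cells) == 0) return(post)
  if (approx) {
    ll <- approx_pooled_loglik(grid, cells)
    cpp_softmax_inplace(ll, log_prior_vec(grid, prior))
    dim(ll) <- grid$sizes
    post$mass <- ll
  } else {
    ll <- exact_pooled_loglik(grid, cells)
    lp <- log(as.vector(post$mass)) + ll
    mx <- max(lp)
    if (!is.finite(mx)) stop("all grid nodes have zero posterior mass")
    w <- exp(lp - mx)
    post$mass <- array(w / sum(w), dim = grid$sizes)
  }
  post
}

# Marginal mass along dimension d of a 5-D mass array.
marginal_mass <- function(post, d) {
  sizes <- post$grid$sizes
  before <- prod(sizes[seq_len(d - 1)])
  nd <- sizes[d]
  after <- prod(sizes)/(before * nd)
  m <- matrix(colSums(matrix(as.vector(post$mass), before, nd * after)),
              nd, after)
  rowSums(m)
}

#' Posterior point estimate (marginal means)
#'
#' The per-dimension marginal posterior mean in log10 grid space; the
#' linear-scale parameters are the exponentiated (base 10) log10 means.
#'
#' @param post A `csf_posterior`.
#' @return A list with `log10` (named numeric vector of marginal means) and
#'   `linear` (the same, exponentiated).
#' @export
point_estimate <- function(post) {
  marg <- cpp_marginals(post$mass, post$grid$sizes)
  l10 <- vapply(seq_len(5), function(d) {
    sum(post$grid$axes[[d]] * marg[[d]])
  }, numeric(1))
  names(l10) <- DIM_NAMES
  list(log10 = l10, linear = stats::setNames(10^l10, DIM_NAMES))
}

#' Estimated contrast sensitivity at given spatial frequencies
#'
#' Evaluates the double-exponential CSF at the posterior point estimate.
#'
#' @param post A `csf_posterior`.
#' @param sfs Spatial frequencies (c/d).
#' @return Sensitivity values, one per frequency.
#' @export
estimated_csf <- function(post, sfs = stimulus_grid()$sfs) {
  est <- point_estimate(post)$linear
  csf_sensitivity(sfs, est[["M"]], est[["A"]], est[["F"]])
}

#' Shannon entropy of a gridded posterior
#'
#' @param post A `csf_posterior`.
#' @return Entropy in nats (`0 log 0` taken as 0).
#' @export
posterior_entropy <- function(post) {
  m <- as.vector(post$mass)
  m <- m[m > 0]
  -sum(m * log(m))
}
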