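# Adaptive stimulus-selection strategies.
#
# All four samplers share one contract: `$propose()` returns the next
# stimulus (always a node of the shared stimulus grid) and
# `$observe(sf, contrast, response)` feeds the response back. Samplers are
# mutable environment objects; all their randomness (interleaving
# schedules, tie-breaks, top-10% draws) comes from a private RNG stream, so
# observer draws are untouched.
#
# The two Bayesian 2-D methods (qCSF-style entropy minimization and Fisher
# information gain) keep an internal posterior for stimulus selection. Its
# grid is configurable and defaults to a coarser discretization than the
# full inference grid: stimulus selection only needs a rough posterior,
# while final estimates are always recomputed on the full grid from the
# complete trial log.

phi_binary <- function(p) {
  out <- numeric(length(p))
  ok <- p > 0 & p < 1
  out[ok] <- p[ok] * log(p[ok]) + (1 - p[ok]) * log1p(-p[ok])
  out
}

# Per-SF trial allocation: exactly budget/nsf each when divisible, with the
# remainder spread over distinct frequencies uniformly at random; the
# resulting multiset is then randomly interleaved.
interleave_schedule <- function(budget, nsf, stream) {
  counts <- rep(budget %/% nsf, nsf)
  rem <- budget %% nsf
  with_rng(stream, {
    if (rem > 0) {
      bump <- sample.int(nsf, rem)
      counts[bump] <- counts[bump] + 1L
    }
    sample(rep(seq_len(nsf), counts))
  })
}

# Sensitivity of the prior-mean CSF, used for staircase starting contrasts
# and the per-frequency Psi prior thresholds.
prior_csf_sensitivity <- function(sfs, prior_mean = c(2.00, -0.30, 0.78)) {
  csf_sensitivity(sfs, 10^prior_mean[1], 10^prior_mean[2], 10^prior_mean[3])
}

#' Create an adaptive stimulus sampler
#'
#' Constructs one of the four adaptive procedures:
#' \describe{
#'   \item{`"staircase"`}{Weighted up-down staircase, one independent
#'     staircase per spatial frequency, randomly interleaved. Contrast steps
#'     up by `up_factor` (default 4/3, about +33\%) after a negative
#'     response and down by `down_factor` (default 0.9) after a positive
#'     one; the first `warmup_trials` (default 4) of each staircase use the
#'     cubed factors. Each staircase starts at the prior-estimated
#'     threshold for its frequency.}
#'   \item{`"psi"`}{Per-frequency Bayesian threshold/slope estimation: one
#'     independent 2-D (alpha, beta) posterior per spatial frequency,
#'     randomly interleaved; each trial picks the contrast minimizing the
#'     expected posterior entropy of that frequency's run.}
#'   \item{`"qcsf"`}{Expected-entropy minimization over the joint
#'     frequency-contrast grid using a 5-D CSF-parameter posterior;
#'     candidate stimuli may be randomly subsampled per trial
#'     (`n_candidates`) for speed.}
#'   \item{`"fig"`}{One-step-ahead D-optimal selection: each candidate is
#'     scored by the determinant of the accumulated Fisher information
#'     matrix plus the candidate's information at the current posterior-mean
#'     parameters, and the stimulus is drawn uniformly among the top
#'     `top_fraction` (default 10\%) of candidates.}
#' }
#'
#' @param method One of `"staircase"`, `"psi"`, `"qcsf"`, `"fig"`.
#' @param budget Total number of trials the sampler will run.
#' @param seed Integer seed for the sampler's private RNG stream.
#' @param stim_grid The [stimulus_grid()] of presentable stimuli.
#' @param options Named list of method options. Common: `prior_mean`
#'   (log10 prior means of M, A, F used for starting points). Staircase:
#'   `up_factor`, `down_factor`, `warmup_trials`. Psi: `n_alpha`, `n_beta`,
#'   `alpha_prior_sd`, `beta_prior_mean`, `beta_prior_sd`, `delta`.
#'   qCSF: `sampler_grid` (a [csf_param_grid()]), `n_candidates`.
#'   FIG: `sampler_grid`, `top_fraction`, `ridge`.
#' @return A mutable sampler object (environment) with `$propose()`,
#'   `$observe(sf, contrast, response)` and, for `"staircase"`/`"psi"`,
#'   `$thresholds()` returning the per-frequency 1-D sensitivity estimates.
#' @examples
#' s <- csf_sampler("staircase", budget = 48, seed = 7)
#' st <- s$propose()
#' s$observe(st$sf, st$contrast, response = 1)
#' @export
csf_sampler <- function(method, budget, seed = 1L,
                        stim_grid = stimulus_grid(), options = list()) {
  allowed <- c("staircase", "psi", "qcsf", "fig")
  if (!is.character(method) || length(method) != 1 || !(method %in% allowed)) {
    stop("unknown sampler `", paste(method, collapse = "/"),
         "`; must be one of: ", paste(allowed, collapse = ", "))
  }
  stopifnot(budget >= 1)
  stream <- new_rng_stream(seed)
  switch(method,
    staircase = sampler_staircase(budget, stream, stim_grid, options),
    psi = sampler_psi(budget, stream, stim_grid, options),
    qcsf = sampler_qcsf(budget, stream, stim_grid, options),
    fig = sampler_fig(budget, stream, stim_grid, options))
}

opt <- function(options, name, default) {
  if (!is.null(options[[name]])) options[[name]] else default
}

# ---- weighted up-down staircase ------------------------------------------

sampler_staircase <- function(budget, stream, stim_grid, options) {
  e <- new.env(parent = emptyenv())
  e$method <- "staircase"
  e$budget <- budget
  nsf <- length(stim_grid$sfs)
  up <- opt(options, "up_factor", 4 / 3)
  down <- opt(options, "down_factor", 0.9)
  warmup <- opt(options, "warmup_trials", 4L)
  prior_mean <- opt(options, "prior_mean", c(2.00, -0.30, 0.78))
  e$schedule <- interleave_schedule(budget, nsf, stream)
  e$t <- 0L
  e$current <- snap_contrast(1 / prior_csf_sensitivity(stim_grid$sfs,
                                                       prior_mean), stim_grid)
  e$count <- integer(nsf)
  e$history <- rep(list(numeric()), nsf)

  e$propose <- function() {
    i <- e$schedule[e$t + 1L]
    list(sf = stim_grid$sfs[i], contrast = e$current[i])
  }
  e$observe <- function(sf, contrast, response) {
    i <- match(sf, stim_grid$sfs)
    stopifnot(!is.na(i), response %in% c(0, 1))
    e$t <- e$t + 1L
    e$count[i] <- e$count[i] + 1L
    e$history[[i]] <- c(e$history[[i]], contrast)
    fac <- if (response == 1) down else up
    if (e$count[i] <= warmup) fac <- fac^3
    e$current[i] <- snap_contrast(contrast * fac, stim_grid)
    invisible(e)
  }
  e$thresholds <- function() {
    vapply(seq_len(nsf), function(i) staircase_threshold(e, i), numeric(1))
  }
  class(e) <- c("stc_sampler", "csf_sampler")
  e
}

#' Staircase 1-D sensitivity estimate for one spatial frequency
#'
#' The reciprocal of the geometric-mean contrast over a staircase's trials
#' after discarding its first four (warmup, accelerated-step) trials. For
#' very short runs that do not extend past the warmup, only as many leading
#' trials as possible are discarded so that at least the final trial always
#' contributes.
#'
#' @param sampler A `"staircase"` sampler created by [csf_sampler()].
#' @param sf_index Index of the spatial frequency in the stimulus grid.
#' @return Sensitivity (1 / threshold contrast).
#' @export
staircase_threshold <- function(sampler, sf_index) {
  h <- sampler$history[[sf_index]]
  if (length(h) == 0) {
    stop("staircase for this frequency has no trials")
  }
  drop <- min(4L, length(h) - 1L)
  1 / exp(mean(log(h[(drop + 1L):length(h)])))
}

# ---- per-frequency Psi method --------------------------------------------

sampler_psi <- function(budget, stream, stim_grid, options) {
  e <- new.env(parent = emptyenv())
  e$method <- "psi"
  e$budget <- budget
  nsf <- length(stim_grid$sfs)
  n_alpha <- opt(options, "n_alpha", 64L)
  n_beta <- opt(options, "n_beta", 8L)
  a_sd <- opt(options, "alpha_prior_sd", 5)
  b_mean <- opt(options, "beta_prior_mean", 0.62)
  b_sd <- opt(options, "beta_prior_sd", 0.11)
  delta <- opt(options, "delta", 0.02)
  gamma <- opt(options, "gamma", 0.5)
  prior_mean <- opt(options, "prior_mean", c(2.00, -0.30, 0.78))
  span <- 2.5

  a_means <- -log10(prior_csf_sensitivity(stim_grid$sfs, prior_mean))
  lo <- pmax(-3, a_means - span * a_sd)
  hi <- pmin(0, a_means + span * a_sd)
  e$alpha_axes <- lapply(seq_len(nsf), function(i) {
    seq(lo[i], hi[i], length.out = n_alpha)
  })
  e$beta_axis <- seq(b_mean - span * b_sd, b_mean + span * b_sd,
                     length.out = n_beta)

  lnc <- log(stim_grid$contrasts)
  make_tables <- function(a_axis) {
    # nodes ordered (alpha, beta), alpha fastest
    lna <- log(10) * a_axis
    P <- matrix(0, n_alpha * n_beta, length(lnc))
    for (k in seq_len(n_beta)) {
      bk <- 10^e$beta_axis[k]
      rows <- (k - 1L) * n_alpha + seq_len(n_alpha)
      P[rows, ] <- gamma + (1 - gamma - delta) *
        stats::plogis(bk * outer(-lna, lnc, "+"))
    }
    list(P = P, PHI = matrix(phi_binary(P), nrow(P)))
  }
  # tables depend only on the axes and the fixed rates, so they are cached
  # at session level and shared across sampler instances
  e$tables <- lapply(seq_len(nsf), function(i) {
    key <- paste("psi-tab", paste(signif(e$alpha_axes[[i]], 12), collapse = ","),
                 paste(signif(e$beta_axis, 12), collapse = ","),
                 gamma, delta, paste(signif(range(lnc), 12), collapse = ","),
                 length(lnc))
    hit <- .csf_cache[[key]]
    if (is.null(hit)) {
      hit <- make_tables(e$alpha_axes[[i]])
      .csf_cache[[key]] <- hit
    }
    hit
  })
  e$mass <- lapply(seq_len(nsf), function(i) {
    w <- as.vector(outer(stats::dnorm(e$alpha_axes[[i]], a_means[i], a_sd),
                         stats::dnorm(e$beta_axis, b_mean, b_sd)))
    w / sum(w)
  })
  e$schedule <- interleave_schedule(budget, nsf, stream)
  e$t <- 0L

  e$propose <- function() {
    i <- e$schedule[e$t + 1L]
    sc <- cpp_score_candidates(e$tables[[i]]$P, e$tables[[i]]$PHI,
                               e$mass[[i]], seq_along(stim_grid$contrasts))
    best <- which(sc$mi == max(sc$mi))
    j <- if (length(best) == 1) best else
      with_rng(stream, best[sample.int(length(best), 1)])
    list(sf = stim_grid$sfs[i], contrast = stim_grid$contrasts[j])
  }
  e$observe <- function(sf, contrast, response) {
    i <- match(sf, stim_grid$sfs)
    j <- match(contrast, stim_grid$contrasts)
    stopifnot(!is.na(i), !is.na(j), response %in% c(0, 1))
    e$t <- e$t + 1L
    lik <- e$tables[[i]]$P[, j]
    if (response == 0) lik <- 1 - lik
    w <- e$mass[[i]] * lik
    tot <- sum(w)
    if (tot <= 0) stop("Psi posterior update degenerated to zero mass")
    e$mass[[i]] <- w / tot
    invisible(e)
  }
  e$thresholds <- function() {
    vapply(seq_len(nsf), function(i) psi_threshold(e, i), numeric(1))
  }
  class(e) <- c("psi_sampler", "csf_sampler")
  e
}

#' Psi-method sensitivity estimate for one spatial frequency
#'
#' The reciprocal of the posterior-mean threshold: sensitivity is
#' `10^(-mean of the log10 alpha marginal)` of that frequency's (alpha,
#' beta) posterior.
#'
#' @param sampler A `"psi"` sampler created by [csf_sampler()].
#' @param sf_index Index of the spatial frequency in the stimulus grid.
#' @return Sensitivity (1 / threshold contrast).
#' @export
psi_threshold <- function(sampler, sf_index) {
  n_alpha <- length(sampler$alpha_axes[[sf_index]])
  w <- sampler$mass[[sf_index]]
  a_marg <- rowSums(matrix(w, n_alpha))
  10^(-sum(sampler$alpha_axes[[sf_index]] * a_marg))
}

# ---- qCSF-style expected-entropy minimization ----------------------------

# Session-level cache of the [nodes x candidates] probability tables; they
# depend only on the sampler grid and stimulus grid, not on the data.
qcsf_tables <- function(grid, stim_grid) {
  key <- paste("qcsf", grid_signature(grid),
               paste(signif(stim_grid$sfs, 12), collapse = ","),
               paste(signif(range(stim_grid$contrasts), 12), collapse = ","),
               length(stim_grid$contrasts))
  hit <- .csf_cache[[key]]
  if (!is.null(hit)) return(hit)
  nsf <- length(stim_grid$sfs)
  ncon <- length(stim_grid$contrasts)
  lnalpha <- node_lnalpha(grid, stim_grid$sfs)
  nmaf <- nrow(lnalpha)
  nb <- grid$sizes[4]; nd <- grid$sizes[5]
  betas <- 10^grid$axes$beta
  deltas <- 10^grid$axes$delta
  g <- grid$gamma
  lnc <- log(stim_grid$contrasts)
  P <- matrix(0, nmaf * nb * nd, nsf * ncon)
  for (i in seq_len(nsf)) {
    t0 <- outer(-lnalpha[, i], lnc, "+")      # [nmaf x ncon]
    cols <- (i - 1L) * ncon + seq_len(ncon)
    for (k in seq_len(nb)) {
      p <- stats::plogis(betas[k] * t0)
      for (m in seq_len(nd)) {
        rows <- ((m - 1L) * nb + (k - 1L)) * nmaf + seq_len(nmaf)
        P[rows, cols] <- g + (1 - g - deltas[m]) * p
      }
    }
  }
  out <- list(P = P, packed = cpp_pack_tables(P), n_nodes = nrow(P))
  .csf_cache[[key]] <- out
  out
}

sampler_qcsf <- function(budget, stream, stim_grid, options) {
  e <- new.env(parent = emptyenv())
  e$method <- "qcsf"
  e$budget <- budget
  grid <- opt(options, "sampler_grid",
              csf_param_grid(sizes = c(8L, 8L, 8L, 5L, 5L)))
  n_cand <- opt(options, "n_candidates", 100L)
  nsf <- length(stim_grid$sfs)
  ncon <- length(stim_grid$contrasts)
  ntot <- nsf * ncon
  tab <- qcsf_tables(grid, stim_grid)
  e$grid <- grid
  post <- build_prior(grid)
  e$mass <- as.vector(post$mass)
  e$t <- 0L


  e$propose <- function() {
    cand <- if (is.null(n_cand) || n_cand >= ntot) seq_len(ntot) else
      with_rng(stream, sample.int(ntot, n_cand))
    # restrict sums to the posterior's numerically relevant support (only
    # worthwhile once the support is substantially smaller than the grid)
    act <- which(e$mass > max(e$mass) * 1e-13)
    if (length(act) > 0.5 * length(e$mass)) act <- NULL
    sc <- cpp_score_candidates_packed(tab$packed, tab$n_nodes, e$mass, cand,
                                      act)
    best <- cand[sc$mi == max(sc$mi)]
    pick <- if (length(best) == 1) best else
      with_rng(stream, best[sample.int(length(best), 1)])
    i <- (pick - 1L) %/% ncon + 1L
    j <- (pick - 1L) %% ncon + 1L
    list(sf = stim_grid$sfs[i], contrast = stim_grid$contrasts[j])
  }
  e$observe <- function(sf, contrast, response) {
    i <- match(sf, stim_grid$sfs)
    j <- match(contrast, stim_grid$contrasts)
    stopifnot(!is.na(i), !is.na(j), response %in% c(0, 1))
    e$t <- e$t + 1L
    lik <- tab$P[, (i - 1L) * length(stim_grid$contrasts) + j]
    if (response == 0) lik <- 1 - lik
    w <- e$mass * lik
    tot <- sum(w)
    if (tot <= 0) stop("qCSF posterior update degenerated to zero mass")
    e$mass <- w / tot
    invisible(e)
  }
  e$posterior <- function() {
    structure(list(grid = grid, mass = array(e$mass, grid$sizes)),
              class = "csf_posterior")
  }
  class(e) <- c("qcsf_sampler", "csf_sampler")
  e
}

# ---- Fisher information gain (D-optimal) ---------------------------------

sampler_fig <- function(budget, stream, stim_grid, options) {
  e <- new.env(parent = emptyenv())
  e$method <- "fig"
  e$budget <- budget
  grid <- opt(options, "sampler_grid",
              csf_param_grid(sizes = c(12L, 12L, 12L, 6L, 6L)))
  frac <- opt(options, "top_fraction", 0.10)
  ridge <- opt(options, "ridge", 1e-8)
  e$grid <- grid
  e$post <- build_prior(grid)
  e$theta <- point_estimate(e$post)
  e$J <- diag(ridge, 4)
  e$t <- 0L
  cand_sf <- rep(stim_grid$sfs, each = length(stim_grid$contrasts))
  cand_con <- rep(stim_grid$contrasts, length(stim_grid$sfs))
  ntot <- length(cand_sf)
  gamma <- grid$gamma

  theta_params <- function() {
    est <- e$theta$linear
    list(M = est[["M"]], A = est[["A"]], F = est[["F"]],
         beta = est[["beta"]], gamma = gamma, delta = est[["delta"]])
  }
  # normalized information vector u(x) with I(x) = u u^T
  info_vec <- function(sf, contrast) {
    th <- theta_params()
    g <- detect_prob_grad(sf, contrast, th)
    P <- detect_prob(sf, contrast, th)
    g / sqrt(pmax(P * (1 - P), 1e-300))
  }

  e$propose <- function() {
    U <- info_vec(cand_sf, cand_con)
    # det(J + u u^T) = det(J) (1 + u^T J^-1 u): rank the quadratic form
    Jinv <- solve(e$J)
    score <- rowSums((U %*% Jinv) * U)
    k <- max(1L, as.integer(floor(frac * ntot)))
    top <- order(score, decreasing = TRUE)[seq_len(k)]
    pick <- with_rng(stream, top[sample.int(k, 1)])
    list(sf = cand_sf[pick], contrast = cand_con[pick])
  }
  e$observe <- function(sf, contrast, response) {
    stopifnot(response %in% c(0, 1))
    e$t <- e$t + 1L
    u <- as.vector(info_vec(sf, contrast))
    e$J <- e$J + tcrossprod(u)
    e$post <- update_posterior(e$post, sf, contrast, response)
    e$theta <- point_estimate(e$post)
    invisible(e)
  }
  e$posterior <- function() e$post
  class(e) <- c("fig_sampler", "csf_sampler")
  e
}

#' @export
print.csf_sampler <- function(x, ...) {
  cat(sprintf("Adaptive sampler `%s`: %d/%d trials observed\n",
              x$method, x$t, x$budget))
  invisible(x)
}
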