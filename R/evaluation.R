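# Monte-Carlo evaluation harness: simulated sessions, dB error metrics and
# the pooled RMSE/bias report comparing sampling strategies with and
# without full 2-D Bayesian re-estimation.

#' Simulate one adaptive testing session against a simulated observer
#'
#' Alternates sampler proposal, observer response and sampler update for
#' `budget` trials. The sampler and the observer draw from independent RNG
#' streams derived from `seed`, so different samplers see identical
#' observer randomness at a matched seed.
#'
#' @param method Sampler name passed to [csf_sampler()].
#' @param budget Number of trials.
#' @param observer An [observer_params()] object or preset name.
#' @param seed Integer session seed.
#' @param stim_grid The [stimulus_grid()].
#' @param sampler_options Options forwarded to [csf_sampler()].
#' @return A list of class `csf_session` with the trial `log` (data frame
#'   `trial, sf_cpd, contrast, response`), the finished `sampler`, the
#'   observer parameters and the seed.
#' @examples
#' run_session("staircase", 48, "normal", seed = 1)$log[1:3, ]
#' @export
run_session <- function(method, budget, observer, seed,
                        stim_grid = stimulus_grid(), sampler_options = list()) {
  if (is.character(observer)) observer <- observer_preset(observer)
  obs <- simulated_observer(observer, seed = derive_seed(seed, "observer"))
  s <- csf_sampler(method, budget, seed = derive_seed(seed, "sampler", method),
                   stim_grid = stim_grid, options = sampler_options)
  sf <- contrast <- numeric(budget)
  response <- integer(budget)
  for (t in seq_len(budget)) {
    st <- s$propose()
    r <- obs$respond(st$sf, st$contrast)
    s$observe(st$sf, st$contrast, r)
    sf[t] <- st$sf; contrast[t] <- st$contrast; response[t] <- r
  }
  structure(list(method = method, budget = budget,
                 log = data.frame(trial = seq_len(budget), sf_cpd = sf,
                                  contrast = contrast, response = response),
                 sampler = s, observer = observer, seed = seed),
            class = "csf_session")
}

#' Per-frequency sensitivity estimates from a finished session
#'
#' Either the sampler's native 1-D estimate (`estimator = "native"`, only
#' for staircase and Psi: mean log contrast / posterior-mean threshold per
#' frequency) or the full 2-D Bayesian estimate recomputed from the trial
#' log (`estimator = "bayes"`, available for any sampler).
#'
#' @param session A [run_session()] result.
#' @param estimator `"native"` or `"bayes"`.
#' @param grid Parameter grid for the Bayesian estimate.
#' @param stim_grid Stimulus grid defining the report frequencies.
#' @param approx Passed to [infer_csf()].
#' @return Sensitivity estimates at each grid frequency.
#' @export
session_estimates <- function(session, estimator = c("bayes", "native"),
                              grid = csf_param_grid(),
                              stim_grid = stimulus_grid(), approx = TRUE) {
  estimator <- match.arg(estimator)
  if (estimator == "native") {
    if (!session$method %in% c("staircase", "psi")) {
      stop("native 1-D estimates exist only for staircase and psi samplers")
    }
    return(session$sampler$thresholds())
  }
  estimated_csf(infer_csf(session$log, grid, approx = approx), stim_grid$sfs)
}

db_sens <- function(s, db_factor = 20) {
  if (any(s <= 0)) stop("sensitivities must be strictly positive")
  db_factor * log10(s)
}

#' Pooled RMSE of estimated versus true sensitivity in decibels
#'
#' The square root of the grand mean of squared errors in sensitivity
#' decibels (`20 log10 S` by default), pooled jointly across all runs and
#' spatial frequencies.
#'
#' @param est Matrix of estimated sensitivities, one row per run, one
#'   column per spatial frequency (a single run may be a vector).
#' @param truth Vector of true sensitivities per frequency (or a matrix
#'   shaped like `est`).
#' @param db_factor Decibel convention: 20 (default) for `20 log10 S`, or
#'   10.
#' @return Pooled RMSE in dB.
#' @examples
#' rmse_db(c(200, 20), c(100, 10))  # constant factor 2: ~6.02 dB
#' @export
rmse_db <- function(est, truth, db_factor = 20) {
  est <- rbind(est)
  err <- sweep(db_sens(est, db_factor), 2,
               rep_len(db_sens(truth, db_factor), ncol(est)))
  sqrt(mean(err^2))
}

#' Mean bias of estimated versus true sensitivity in decibels
#'
#' The grand mean of `db(est) - db(truth)` pooled across runs and
#' frequencies (positive = overestimation).
#'
#' @inheritParams rmse_db
#' @return Mean bias in dB.
#' @export
bias_db <- function(est, truth, db_factor = 20) {
  est <- rbind(est)
  err <- sweep(db_sens(est, db_factor), 2,
               rep_len(db_sens(truth, db_factor), ncol(est)))
  mean(err)
}

#' Area under the log contrast sensitivity function
#'
#' Trapezoidal integral of `log10 S(f)` against `log2 f` across the sampled
#' spatial frequencies; a scalar summary of the whole CSF.
#'
#' @param sens Sensitivities at `sfs`.
#' @param sfs Spatial frequencies (c/d).
#' @return The area value.
#' @export
aulcsf <- function(sens, sfs = stimulus_grid()$sfs) {
  stopifnot(length(sens) == length(sfs), all(sens > 0))
  x <- log2(sfs)
  y <- log10(sens)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Map requested estimate labels onto the sampling method that collects the
# data. "bayes_stc" and "stc" (likewise "bayes_psi"/"psi") reuse the same
# sampled trial log.
SAMPLING_OF <- c(fig = "fig", qcsf = "qcsf", psi = "psi", stc = "staircase",
                 bayes_psi = "psi", bayes_stc = "staircase",
                 bayes_fig = "fig", bayes_qcsf = "qcsf")
ESTIMATOR_OF <- c(fig = "bayes", qcsf = "bayes", psi = "native",
                  stc = "native", bayes_psi = "bayes", bayes_stc = "bayes",
                  bayes_fig = "bayes", bayes_qcsf = "bayes")

#' Monte-Carlo comparison of sampling strategies
#'
#' Runs `N` simulated sessions per trial budget, computes per-frequency
#' sensitivity estimates for each requested method label, and reports the
#' pooled RMSE and mean bias in dB with run-level bootstrap standard
#' errors. Method labels combine a sampling strategy and an estimator:
#' `"fig"` and `"qcsf"` are 2-D samplers with the full Bayesian estimate;
#' `"psi"` and `"stc"` are the 1-D samplers with their native per-frequency
#' estimates; `"bayes_psi"` and `"bayes_stc"` apply the full 2-D Bayesian
#' estimate to the *same* trial logs as `"psi"`/`"stc"`.
#'
#' @param methods Character vector of method labels (see Details).
#' @param budgets Integer vector of trial budgets.
#' @param observer Observer parameters or preset name.
#' @param N Number of Monte-Carlo runs per budget.
#' @param base_seed Integer seed; run `i` of budget `b` derives its own
#'   session seed from it.
#' @param grid Parameter grid for Bayesian estimates.
#' @param stim_grid Stimulus grid.
#' @param approx Use the fast table-interpolation likelihood kernel.
#' @param sampler_options Per-sampling-method option lists, e.g.
#'   `list(qcsf = list(n_candidates = 50))`.
#' @param n_boot Bootstrap resamples for the standard errors.
#' @param db_factor Decibel convention (20 or 10).
#' @param keep_estimates If `TRUE`, attach the per-run estimate matrices as
#'   attribute `"estimates"`.
#' @param progress Print one line per (budget, method) block.
#' @return A data frame with one row per (method, budget):
#'   `method, budget, n_runs, rmse_db, bias_db, rmse_se, bias_se,
#'   aulcsf_mean, aulcsf_sd`.
#' @export
monte_carlo <- function(methods = c("fig", "qcsf", "bayes_psi", "bayes_stc",
                                    "psi", "stc"),
                        budgets = 108L, observer = "normal", N = 100L,
                        base_seed = 1L, grid = csf_param_grid(),
                        stim_grid = stimulus_grid(), approx = TRUE,
                        sampler_options = list(), n_boot = 1000L,
                        db_factor = 20, keep_estimates = FALSE,
                        progress = FALSE) {
  stopifnot(N >= 1, all(methods %in% names(SAMPLING_OF)))
  if (is.character(observer)) observer <- observer_preset(observer)
  truth <- csf_sensitivity(stim_grid$sfs, observer$M, observer$A, observer$F)
  out <- list(); est_keep <- list()
  for (b in budgets) {
    samplers_needed <- unique(unname(SAMPLING_OF[methods]))
    est <- lapply(stats::setNames(methods, methods), function(m) {
      matrix(NA_real_, N, length(stim_grid$sfs))
    })
    for (i in seq_len(N)) {
      seed_i <- derive_seed(base_seed, "run", b, i)
      sessions <- lapply(stats::setNames(samplers_needed, samplers_needed),
        function(sm) run_session(sm, b, observer, seed_i, stim_grid,
                                 opt(sampler_options, sm, list())))
      for (m in methods) {
        est[[m]][i, ] <- session_estimates(
          sessions[[SAMPLING_OF[[m]]]], ESTIMATOR_OF[[m]], grid, stim_grid,
          approx = approx)
      }
    }
    for (m in methods) {
      met <- pooled_metrics(est[[m]], truth, n_boot = n_boot,
                            db_factor = db_factor,
                            boot_seed = derive_seed(base_seed, "boot", b, m))
      out[[length(out) + 1L]] <- data.frame(
        method = m, budget = b, n_runs = N,
        rmse_db = met$rmse, bias_db = met$bias,
        rmse_se = met$rmse_se, bias_se = met$bias_se,
        aulcsf_mean = met$aulcsf_mean, aulcsf_sd = met$aulcsf_sd)
      if (progress) {
        message(sprintf("budget %d  %-9s rmse %.2f dB  bias %+.2f dB", b, m,
                        met$rmse, met$bias))
      }
      if (keep_estimates) est_keep[[paste(m, b, sep = "_")]] <- est[[m]]
    }
  }
  res <- do.call(rbind, out)
  if (keep_estimates) attr(res, "estimates") <- est_keep
  res
}

#' Pooled metrics with run-level bootstrap errors
#'
#' @param est Matrix of estimates, runs by frequencies.
#' @param truth True sensitivities per frequency.
#' @param n_boot Bootstrap resamples (resampling whole runs).
#' @param db_factor Decibel convention.
#' @param boot_seed Seed for the bootstrap resampling stream.
#' @param sfs Spatial frequencies for the AULCSF summary.
#' @return List with `rmse`, `bias`, `rmse_se`, `bias_se`, `aulcsf_mean`,
#'   `aulcsf_sd`.
#' @export
pooled_metrics <- function(est, truth, n_boot = 1000L, db_factor = 20,
                           boot_seed = 1L, sfs = stimulus_grid()$sfs) {
  est <- rbind(est)
  err <- sweep(db_sens(est, db_factor), 2, db_sens(truth, db_factor))
  n <- nrow(err)
  sq_run <- rowMeans(err^2)   # per-run mean squared error
  mn_run <- rowMeans(err)
  boot <- with_rng(new_rng_stream(boot_seed), {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    list(rmse = apply(idx, 1, function(j) sqrt(mean(sq_run[j]))),
         bias = apply(idx, 1, function(j) mean(mn_run[j])))
  })
  au <- if (ncol(est) == length(sfs)) apply(est, 1, aulcsf, sfs = sfs) else NA_real_
  list(rmse = sqrt(mean(sq_run)), bias = mean(mn_run),
       rmse_se = stats::sd(boot$rmse), bias_se = stats::sd(boot$bias),
       aulcsf_mean = mean(au),
       aulcsf_sd = if (length(au) > 1) stats::sd(au) else NA_real_)
}
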