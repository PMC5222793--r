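# Trial-log and configuration round-tripping, plus the three command-level
# entry points (`cmd_simulate`, `cmd_infer`, `cmd_evaluate`) that the
# Rscript wrapper in `inst/cli/csfbayes.R` exposes on the shell.
#
# Trial logs are plain CSV (`trial,sf_cpd,contrast,response`) so data
# collected by other software can be fed straight into the Bayesian
# inference; configs are JSON or YAML.

#' Read a trial log CSV
#'
#' Expects (at least) the columns `trial`, `sf_cpd`, `contrast`,
#' `response`; extra columns are tolerated and ignored.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the four canonical columns.
#' @export
read_trial_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "sf_cpd", "contrast", "response")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(d) == 0) stop("trial log is empty")
  if (!all(d$response %in% c(0, 1))) {
    stop("trial log responses must be 0 or 1")
  }
  if (any(d$contrast <= 0) || any(d$sf_cpd <= 0)) {
    stop("contrasts and spatial frequencies must be strictly positive")
  }
  d[, need]
}

#' Write a trial log CSV
#'
#' Contrast is written with full precision; the write is atomic
#' (temp-file-then-rename).
#'
#' @param log Data frame with columns `trial`, `sf_cpd`, `contrast`,
#'   `response`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(format(log, digits = 15, trim = TRUE, scientific = FALSE),
                     tmp, row.names = FALSE, quote = FALSE)
  })
}

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' @param path Path ending in `.json`, `.yaml` or `.yml`.
#' @return A named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format `.", ext, "`; use .json, .yaml or .yml"))
  validate_config(cfg)
}

CONFIG_KEYS <- c("observer", "sampler", "trials", "seed", "grid", "prior",
                 "stimulus", "n_runs", "methods", "budgets", "db_factor",
                 "approx")

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  bad <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(CONFIG_KEYS, collapse = ", "), ")")
  }
  if (!is.null(cfg$sampler)) {
    nm <- if (is.list(cfg$sampler)) cfg$sampler$name else cfg$sampler
    if (!nm %in% c("staircase", "psi", "qcsf", "fig")) {
      stop("config key `sampler`: unknown sampler `", nm,
           "`; must be one of: staircase, psi, qcsf, fig")
    }
  }
  cfg
}

config_observer <- function(cfg) {
  o <- cfg$observer
  if (is.null(o)) return(observer_preset("normal"))
  if (is.character(o)) return(observer_preset(o))
  if (!is.null(o$preset)) return(observer_preset(o$preset))
  observer_params(M = o$M, A = o$A, F = o$F, beta = o$beta,
                  gamma = if (is.null(o$gamma)) 0.5 else o$gamma,
                  delta = if (is.null(o$delta)) 0.02 else o$delta)
}

config_grid <- function(cfg) {
  g <- cfg$grid
  p <- cfg$prior
  args <- list()
  if (!is.null(g$sizes)) args$sizes <- as.integer(g$sizes)
  if (!is.null(g$span_sd)) args$span_sd <- g$span_sd
  if (!is.null(p$mean)) args$prior_mean <- as.numeric(p$mean)
  if (!is.null(p$diag)) args$prior_diag <- as.numeric(p$diag)
  if (!is.null(p$diag_is_sd)) args$diag_is_sd <- isTRUE(p$diag_is_sd)
  if (!is.null(g$gamma)) args$gamma <- g$gamma
  do.call(csf_param_grid, args)
}

config_stim_grid <- function(cfg) {
  s <- cfg$stimulus
  if (is.null(s)) return(stimulus_grid())
  args <- list()
  if (!is.null(s$sfs)) args$sfs <- as.numeric(s$sfs)
  if (!is.null(s$contrasts)) args$contrasts <- as.numeric(s$contrasts)
  do.call(stimulus_grid, args)
}

config_sampler_name <- function(cfg) {
  if (is.null(cfg$sampler)) return("staircase")
  if (is.list(cfg$sampler)) cfg$sampler$name else cfg$sampler
}

config_sampler_options <- function(cfg) {
  if (is.list(cfg$sampler)) cfg$sampler[setdiff(names(cfg$sampler), "name")]
  else list()
}

#' Simulate one session from a configuration and write its trial log
#'
#' Runs a single seeded sampler-plus-observer session and writes the CSV
#' trial log together with a JSON sidecar echoing the effective
#' configuration (for provenance).
#'
#' @param config Config list (see [read_config()]) or path to a config
#'   file.
#' @param seed Session seed (overrides `config$seed` if given).
#' @param out_dir Output directory.
#' @return Invisibly, the path of the written trial log.
#' @export
cmd_simulate <- function(config, seed = NULL, out_dir = ".") {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  seed <- if (!is.null(seed)) seed else if (!is.null(cfg$seed)) cfg$seed else 1L
  budget <- if (!is.null(cfg$trials)) cfg$trials else 108L
  method <- config_sampler_name(cfg)
  observer <- config_observer(cfg)
  ses <- run_session(method, budget, observer, seed,
                     stim_grid = config_stim_grid(cfg),
                     sampler_options = config_sampler_options(cfg))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, sprintf("trials_%s_seed%d.csv", method, seed))
  write_trial_log(ses$log, log_path)
  sidecar <- list(config = cfg, method = method, trials = budget, seed = seed,
                  observer = unclass(observer), package = "csfbayes")
  atomic_write(sub("\\.csv$", ".json", log_path), function(tmp) {
    jsonlite::write_json(sidecar, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(log_path)
}

#' Infer the CSF from a trial log and write the estimate as JSON
#'
#' Runs the full gridded Bayesian inference on a trial log collected with
#' *any* sampling procedure and writes point estimates (log10 and linear),
#' per-frequency sensitivities, posterior marginal summaries, and an echo
#' of the grid/prior configuration.
#'
#' @param log_file Path to the trial-log CSV.
#' @param config Config list or path (grid/prior/stimulus sections are
#'   honoured).
#' @param out_file Destination JSON path.
#' @return Invisibly, the result list that was written.
#' @export
cmd_infer <- function(log_file, config = list(), out_file = "csf_estimate.json") {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  trials <- read_trial_log(log_file)
  grid <- config_grid(cfg)
  stim <- config_stim_grid(cfg)
  approx <- if (is.null(cfg$approx)) TRUE else isTRUE(cfg$approx)
  post <- infer_csf(trials, grid, approx = approx)
  est <- point_estimate(post)
  marg_sd <- vapply(seq_len(5), function(d) {
    m <- marginal_mass(post, d)
    sqrt(sum(m * (post$grid$axes[[d]] - est$log10[d])^2))
  }, numeric(1))
  res <- list(
    n_trials = nrow(trials),
    log10_mean = as.list(est$log10),
    log10_marginal_sd = as.list(stats::setNames(marg_sd, DIM_NAMES)),
    linear = as.list(est$linear),
    peak_sf_cpd = unname(est$linear[["A"]] * est$linear[["F"]]),
    sensitivity = list(sf_cpd = stim$sfs,
                       sensitivity = estimated_csf(post, stim$sfs)),
    grid = list(sizes = post$grid$sizes,
                prior_mean = post$grid$prior_mean,
                prior_sd = post$grid$prior_sd,
                gamma = post$grid$gamma))
  atomic_write(out_file, function(tmp) {
    jsonlite::write_json(res, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(res)
}

#' Run the Monte-Carlo evaluation and write metrics files
#'
#' Drives [monte_carlo()] from a configuration and writes the metrics both
#' as JSON and as a tidy CSV
#' (`method,budget,n_runs,rmse_db,bias_db,rmse_se,bias_se`).
#'
#' @param config Config list or path. Recognised keys: `methods`,
#'   `budgets`, `n_runs`, `observer`, `grid`, `prior`, `stimulus`, `seed`,
#'   `db_factor`, `approx`.
#' @param n Number of runs (overrides `config$n_runs`).
#' @param out_dir Output directory for `metrics.json` and `metrics.csv`.
#' @param progress Print progress lines.
#' @return Invisibly, the metrics data frame.
#' @export
cmd_evaluate <- function(config = list(), n = NULL, out_dir = ".",
                         progress = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  n <- if (!is.null(n)) n else if (!is.null(cfg$n_runs)) cfg$n_runs else 100L
  methods <- if (!is.null(cfg$methods)) cfg$methods else
    c("fig", "qcsf", "bayes_psi", "bayes_stc", "psi", "stc")
  budgets <- if (!is.null(cfg$budgets)) as.integer(cfg$budgets) else 108L
  seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  db_factor <- if (!is.null(cfg$db_factor)) cfg$db_factor else 20
  res <- monte_carlo(methods = methods, budgets = budgets,
                     observer = config_observer(cfg), N = n, base_seed = seed,
                     grid = config_grid(cfg),
                     stim_grid = config_stim_grid(cfg),
                     approx = if (is.null(cfg$approx)) TRUE else isTRUE(cfg$approx),
                     db_factor = db_factor, progress = progress)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  atomic_write(file.path(out_dir, "metrics.csv"), function(tmp) {
    utils::write.csv(res[, c("method", "budget", "n_runs", "rmse_db",
                             "bias_db", "rmse_se", "bias_se")],
                     tmp, row.names = FALSE)
  })
  atomic_write(file.path(out_dir, "metrics.json"), function(tmp) {
    jsonlite::write_json(list(config = cfg, n_runs = n, metrics = res),
                         tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(res)
}
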