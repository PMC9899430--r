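# File formats: trajectory CSV (t,value,scale,discard_flag[,replicate]),
# posterior draws CSV (chain,iter,parameter,value), summary/manifest JSON,
# experiment config YAML. Numeric values are serialised with 17 significant
# digits so a write/read round trip is bit-faithful.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a trajectory to CSV
#'
#' Columns `t,value,scale,discard_flag` with a mandatory header;
#' `discard_flag` is TRUE for the initial value and the transient steps.
#'
#' @param traj A [new_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pop_trajectory"))
  d <- data.frame(
    t = traj$t,
    value = fmt17(traj$value),
    scale = attr(traj, "scale"),
    discard_flag = traj$t <= attr(traj, "n_discard")
  )
  tryCatch(
    write.csv(d, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_io(sprintf("Cannot write trajectory CSV to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Accepts the dialect written by [write_trajectory_csv()]. The number of
#' transient steps is recovered from the `discard_flag` column.
#'
#' @param path Input CSV path.
#' @return A [new_trajectory()] with `source = "external"`.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("File not found: '%s'.", path))
  d <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_io(sprintf("Cannot parse '%s': %s", path, conditionMessage(e)))
  )
  required <- c("t", "value", "scale", "discard_flag")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop_io(sprintf(
      "Malformed trajectory CSV '%s': missing column(s) %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
  d <- d[order(d$t), ]
  values <- suppressWarnings(as.numeric(d$value))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop_io(sprintf("Malformed trajectory CSV '%s': non-numeric value at data line %d.", path, bad))
  }
  flags <- as.logical(d$discard_flag)
  n_discard <- sum(flags & d$t > 0)
  new_trajectory(values,
    scale = d$scale[[1L]], n_discard = n_discard,
    source = "external"
  )
}

#' Write an ensemble to a single long-format CSV
#'
#' Long dialect with a leading `replicate` column.
#'
#' @param ensemble List of trajectories from [generate_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  d <- ensemble_tbl(ensemble)
  d$value <- fmt17(d$value)
  tryCatch(
    write.csv(as.data.frame(d), path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_io(sprintf("Cannot write ensemble CSV to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Write posterior draws to long-format CSV
#'
#' Columns `chain,iter,parameter,value`.
#'
#' @param fit A `ddvar_bayes` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "ddvar_bayes"))
  d <- as.data.frame(fit$draws)
  d$value <- fmt17(d$value)
  tryCatch(
    write.csv(d, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_io(sprintf("Cannot write draws CSV to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Posterior summary of a fit as a JSON-ready list
#'
#' @param fit A `ddvar_bayes` fit.
#' @return A list with the model tag, per-parameter summaries, settings and
#'   convergence flags; pass to [jsonlite::write_json()] or
#'   [write_summary_json()].
#' @export
fit_summary_list <- function(fit) {
  stopifnot(inherits(fit, "ddvar_bayes"))
  list(
    model = fit$model,
    n_obs = fit$n_obs,
    parameters = fit$summary,
    settings = list(
      n_chains = fit$settings$n_chains, n_iter = fit$settings$n_iter,
      n_burn = fit$settings$n_burn, thin = fit$settings$thin,
      seed = fit$settings$seed
    ),
    n_nonstationary_draws = fit$n_nonstationary,
    converged = fit$converged
  )
}

#' Write a posterior summary (or any list) as JSON
#'
#' @param x A list, e.g. from [fit_summary_list()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  tryCatch(
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    error = function(e) stop_io(sprintf("Cannot write JSON to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

config_schema <- list(
  top = c(
    "sigma2_grid", "r_grid", "k", "n_steps", "n_discard", "n_replicates",
    "models_to_fit", "seed", "mcmc"
  ),
  mcmc = c("n_chains", "n_iter", "n_burn", "thin", "seed")
)

#' Read an experiment configuration from YAML
#'
#' Keys mirror the arguments of [experiment_config()]; an `mcmc` block maps
#' to [mcmc_settings()]. Unknown keys are a schema error (listed in the
#' message), so typos never silently fall back to defaults. Missing keys
#' take the defaults, which are the reference simulation design.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("Config file not found: '%s'.", path))
  raw <- tryCatch(yaml::read_yaml(path),
    error = function(e) stop_io(sprintf("Cannot parse YAML '%s': %s", path, conditionMessage(e)))
  )
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_schema$top)
  if (length(unknown)) {
    stop_invalid_input(sprintf(
      "Unknown config key(s): %s. Allowed: %s.",
      paste(unknown, collapse = ", "), paste(config_schema$top, collapse = ", ")
    ))
  }
  mcmc_raw <- raw$mcmc %||% list()
  unknown_m <- setdiff(names(mcmc_raw), config_schema$mcmc)
  if (length(unknown_m)) {
    stop_invalid_input(sprintf(
      "Unknown mcmc config key(s): %s. Allowed: %s.",
      paste(unknown_m, collapse = ", "), paste(config_schema$mcmc, collapse = ", ")
    ))
  }
  mcmc <- do.call(mcmc_settings, mcmc_raw)
  args <- raw[setdiff(names(raw), "mcmc")]
  args$mcmc <- mcmc
  if (!is.null(args$models_to_fit)) args$models_to_fit <- as.character(args$models_to_fit)
  do.call(experiment_config, args)
}

config_as_list <- function(config) {
  list(
    sigma2_grid = config$sigma2_grid, r_grid = config$r_grid, k = config$k,
    n_steps = config$n_steps, n_discard = config$n_discard,
    n_replicates = config$n_replicates,
    models_to_fit = as.list(config$models_to_fit),
    seed = config$seed,
    mcmc = list(
      n_chains = config$mcmc$n_chains, n_iter = config$mcmc$n_iter,
      n_burn = config$mcmc$n_burn, thin = config$mcmc$thin,
      seed = config$mcmc$seed
    )
  )
}

#' Build a run manifest
#'
#' Captures everything needed to reproduce a run bit-for-bit with the same
#' package version: the configuration snapshot, the master seed, record
#' counts and warning tallies.
#'
#' @param config The [experiment_config()] used.
#' @param records Optional records tibble from [run_experiment()].
#' @return A manifest list; serialise with [write_summary_json()].
#' @export
run_manifest <- function(config, records = NULL) {
  m <- list(
    package = "ddvar",
    version = as.character(packageVersion("ddvar")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_as_list(config),
    n_cells = length(config$sigma2_grid) * length(config$r_grid)
  )
  if (!is.null(records)) {
    m$n_records <- nrow(records)
    m$n_flagged <- sum(records$flags != "")
    m$flag_counts <- as.list(table(unlist(strsplit(
      records$flags[records$flags != ""], ","
    ))))
  }
  m
}
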