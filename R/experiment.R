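#' Configuration of the replicated decomposition experiment
#'
#' The defaults reproduce the reference simulation design: Gompertz
#' trajectories of 300 steps with the first 200 discarded, log carrying
#' capacity fixed at 1 (so population density is measured in units of the
#' carrying capacity and `beta = 1 - r`), environmental variance in
#' \{0.10, 0.15, 0.20, 0.25\}, growth rates \{0.8, 0.6, 0.4\} (i.e.
#' `beta` in \{0.2, 0.4, 0.6\}) and 100 replicates per cell, with both the
#' Gompertz and Ricker models fitted to each Gompertz-simulated replicate.
#'
#' @param sigma2_grid Environmental variances to simulate.
#' @param r_grid Intrinsic growth rates to simulate.
#' @param k Log carrying capacity (fixed across cells).
#' @param n_steps,n_discard Steps per trajectory and leading transient steps
#'   excluded from stationary summaries.
#' @param n_replicates Replicated trajectories per design cell.
#' @param mcmc An [mcmc_settings()] object used for every fit (its seed
#'   field is ignored; per-replicate seeds are derived from `seed`).
#' @param models_to_fit Subset of `c("gompertz", "ricker")`; may be empty
#'   (`character()`) to run only the known-variance pathway.
#' @param seed Master seed from which all per-cell, per-replicate simulation
#'   and sampler seeds are derived.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sigma2_grid = c(0.10, 0.15, 0.20, 0.25),
                              r_grid = c(0.8, 0.6, 0.4),
                              k = 1,
                              n_steps = 300L, n_discard = 200L,
                              n_replicates = 100L,
                              mcmc = mcmc_settings(),
                              models_to_fit = c("gompertz", "ricker"),
                              seed = 1L) {
  if (!length(sigma2_grid) || any(sigma2_grid < 0)) {
    stop_invalid_parameter("`sigma2_grid` must be non-empty and >= 0.")
  }
  if (!length(r_grid) || any(r_grid <= 0)) {
    stop_invalid_parameter("`r_grid` must be non-empty and > 0.")
  }
  check_number(k, "k")
  n_steps <- check_count(n_steps, "n_steps")
  n_discard <- check_count(n_discard, "n_discard", min = 0L)
  if (n_discard >= n_steps) stop_invalid_input("`n_discard` must be < `n_steps`.")
  n_replicates <- check_count(n_replicates, "n_replicates")
  stopifnot(inherits(mcmc, "mcmc_settings"))
  if (length(models_to_fit)) {
    models_to_fit <- match.arg(models_to_fit, c("gompertz", "ricker"), several.ok = TRUE)
  }
  check_number(seed, "seed")
  structure(
    list(
      sigma2_grid = sigma2_grid, r_grid = r_grid, k = k,
      n_steps = n_steps, n_discard = n_discard, n_replicates = n_replicates,
      mcmc = mcmc, models_to_fit = models_to_fit, seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Empirical stationary variance of a trajectory
#'
#' Unbiased sample variance (denominator `n - 1`) of the retained
#' stationary segment.
#'
#' @param traj A [new_trajectory()] with a stationary segment of length
#'   >= 2.
#' @return The empirical stationary variance.
#' @export
empirical_stationary_variance <- function(traj) {
  seg <- stationary_segment(traj)
  if (length(seg) < 2L) {
    stop_invalid_input("Stationary segment must have length >= 2 to compute a variance.")
  }
  var(seg)
}

#' Empirical decomposition of a stationary variance
#'
#' Splits an observed stationary variance into an environmental part (the
#' supplied estimate `sigma2_hat`, typically a posterior mean) and the
#' density-dependent remainder `sigma2_dd = v_inf - sigma2_hat`, with
#' `phi_dd = sigma2_dd / v_inf`. When sampling noise makes
#' `sigma2_hat > v_inf` the negative component is kept and flagged rather
#' than clipped: clipping would bias ensemble summaries upward.
#'
#' @param v_inf Empirical stationary variance (> 0).
#' @param sigma2_hat Environmental variance estimate (>= 0).
#' @return A one-row tibble with `v_inf`, `sigma2_env`, `sigma2_dd`,
#'   `phi_dd` and logical `negative` flag.
#' @export
#' @examples
#' decompose_empirical(0.15625, 0.10) # phi_dd = 0.36
decompose_empirical <- function(v_inf, sigma2_hat) {
  check_number(v_inf, "v_inf")
  check_number(sigma2_hat, "sigma2_hat")
  if (v_inf <= 0) stop_invalid_input("`v_inf` must be > 0.")
  if (sigma2_hat < 0) stop_invalid_input("`sigma2_hat` must be >= 0.")
  sigma2_dd <- v_inf - sigma2_hat
  tibble::tibble(
    v_inf = v_inf,
    sigma2_env = sigma2_hat,
    sigma2_dd = sigma2_dd,
    phi_dd = sigma2_dd / v_inf,
    negative = sigma2_dd < 0
  )
}

# Seed bookkeeping: each design cell gets a disjoint block of seeds derived
# from the master seed; simulation and sampler seeds within a replicate are
# offset so their random streams never coincide.
cell_seed <- function(seed, cell_index) seed + 10000L * (cell_index - 1L)

#' Run the replicated variance-decomposition experiment
#'
#' For every design cell (`sigma2` x `r`) simulates `n_replicates` Gompertz
#' trajectories started at the log carrying capacity, computes each
#' replicate's empirical stationary variance, and decomposes it along two
#' pathways: the known-variance pathway (environmental variance set to the
#' generating value) and, for each model in `models_to_fit`, the fitted
#' pathway using that model's posterior mean of `sigma2`. Fits see only the
#' retained stationary segment (the replicate's analysis data, e.g. the
#' last 100 points of the default design), on the log scale for the
#' Gompertz fit and exponentiated for the Ricker fit. Replicates whose
#' chains fail the Gelman-Rubin threshold or produce non-stationary `beta`
#' draws are flagged in their records, never dropped.
#'
#' @param config An [experiment_config()].
#' @param progress Print a line per design cell while running.
#' @return A tibble with one row per (cell x replicate x pathway):
#'   `sigma2_true`, `r_true`, `beta_true`, `replicate`, `model` (one of
#'   `"known"`, `"gompertz"`, `"ricker"`), `v_inf`, `sigma2_hat`,
#'   `sigma2_dd`, `phi_dd`, `rhat_max`, `flags`.
#' @export
run_experiment <- function(config = experiment_config(), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- tidyr::expand_grid(
    sigma2_true = config$sigma2_grid,
    r_true = config$r_grid
  )
  purrr::pmap_dfr(
    list(grid$sigma2_true, grid$r_true, seq_len(nrow(grid))),
    function(sigma2_true, r_true, cell) {
      beta_true <- beta_from_rk(r_true, config$k)
      params <- gompertz_params(r_true, config$k, sigma2_true)
      base_seed <- cell_seed(config$seed, cell)
      if (progress) {
        message(sprintf(
          "cell %d: sigma2 = %.2f, r = %.2f (beta = %.2f)",
          cell, sigma2_true, r_true, beta_true
        ))
      }
      ensemble <- generate_ensemble(
        "gompertz", params,
        n_replicates = config$n_replicates,
        n_steps = config$n_steps, n_discard = config$n_discard,
        base_seed = base_seed
      )
      purrr::imap_dfr(ensemble, function(traj, i) {
        seg <- stationary_segment(traj) # the retained data points are the analysis data
        v_inf <- empirical_stationary_variance(traj)
        rows <- list(record_row(
          sigma2_true, r_true, beta_true, i, "known",
          decompose_empirical(v_inf, sigma2_true),
          rhat_max = NA_real_, extra_flags = character()
        ))
        for (model in config$models_to_fit) {
          fit_settings <- config$mcmc
          fit_settings$seed <- base_seed + i + 500000L
          fit <- if (model == "gompertz") {
            fit_gompertz_bayes(seg, fit_settings)
          } else {
            fit_ricker_bayes(exp(seg), fit_settings)
          }
          flags <- character()
          if (!fit$converged) flags <- c(flags, "rhat_high")
          if (fit$n_nonstationary > 0) flags <- c(flags, "nonstationary_draws")
          rows[[length(rows) + 1L]] <- record_row(
            sigma2_true, r_true, beta_true, i, model,
            decompose_empirical(v_inf, posterior_mean(fit, "sigma2")),
            rhat_max = max(fit$summary$rhat, na.rm = TRUE),
            extra_flags = flags
          )
        }
        dplyr::bind_rows(rows)
      })
    }
  )
}

record_row <- function(sigma2_true, r_true, beta_true, replicate, model,
                       decomp, rhat_max, extra_flags) {
  flags <- extra_flags
  if (decomp$negative) flags <- c(flags, "negative_phi_dd")
  tibble::tibble(
    sigma2_true = sigma2_true, r_true = r_true, beta_true = beta_true,
    replicate = replicate, model = model,
    v_inf = decomp$v_inf, sigma2_hat = decomp$sigma2_env,
    sigma2_dd = decomp$sigma2_dd, phi_dd = decomp$phi_dd,
    rhat_max = rhat_max,
    flags = paste(flags, collapse = ",")
  )
}

#' Summarise experiment records per design cell and model
#'
#' Produces, for each (`sigma2_true`, `beta_true`, `model`) cell, the
#' box-and-whisker summaries of the per-replicate empirical stationary
#' variance and of the density-dependent proportion `phi_dd` (median,
#' quartiles, whiskers at Q1 - 1.5 IQR and Q3 + 1.5 IQR), together with the
#' across-replicate mean of `phi_dd`, its 2.5-97.5 percentile interval, a
#' normal-approximation 95% CI of the mean, and the theoretical value
#' `beta_true^2` for comparison.
#'
#' @param records Output of [run_experiment()].
#' @return A tibble with one row per (cell x model).
#' @export
summarize_experiment <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_invalid_input("`records` must be a non-empty data frame of experiment records.")
  }
  box <- function(x, prefix) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    out <- tibble::tibble(
      q1 = q[1L], median = q[2L], q3 = q[3L],
      whisker_low = q[1L] - 1.5 * iqr, whisker_high = q[3L] + 1.5 * iqr
    )
    stats::setNames(out, paste0(prefix, "_", names(out)))
  }
  records |>
    dplyr::group_by(.data$sigma2_true, .data$r_true, .data$beta_true, .data$model) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      se_mean <- sd(d$phi_dd) / sqrt(n)
      dplyr::bind_cols(
        box(d$v_inf, "v_inf"),
        box(d$phi_dd, "phi_dd"),
        tibble::tibble(
          n_replicates = n,
          phi_dd_mean = mean(d$phi_dd),
          phi_dd_p2.5 = quantile(d$phi_dd, 0.025, names = FALSE),
          phi_dd_p97.5 = quantile(d$phi_dd, 0.975, names = FALSE),
          phi_dd_mean_ci_low = mean(d$phi_dd) - 1.96 * se_mean,
          phi_dd_mean_ci_high = mean(d$phi_dd) + 1.96 * se_mean,
          phi_dd_theory = key$beta_true^2,
          n_flagged = sum(d$flags != "")
        )
      )
    }) |>
    dplyr::ungroup()
}
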