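#' MCMC sampler settings
#'
#' Defaults follow the simulation study design: 3 chains of 14,000
#' iterations with a 4,000-iteration burn-in (convergence of these AR-type
#' models typically needs no more than a couple of thousand iterations, so
#' the burn-in is generous) and no thinning. Proposal scales are starting
#' values only: they adapt in batches during burn-in and are frozen for the
#' retained phase.
#'
#' @param n_chains Number of chains (>= 2, so the Gelman-Rubin diagnostic is
#'   defined).
#' @param n_iter Total iterations per chain.
#' @param n_burn Burn-in iterations discarded per chain (< `n_iter`).
#' @param thin Keep every `thin`-th retained draw.
#' @param seed Integer RNG seed; the whole fit is a pure function of
#'   (data, settings, seed).
#' @param proposal_scales Named numeric vector of initial random-walk
#'   proposal standard deviations.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3L, n_iter = 14000L, n_burn = 4000L,
                          thin = 1L, seed = 1L,
                          proposal_scales = c(r = 0.1, beta = 0.1, K = 0.3, sigma2 = 0.3)) {
  n_chains <- check_count(n_chains, "n_chains", min = 2L)
  n_iter <- check_count(n_iter, "n_iter")
  n_burn <- check_count(n_burn, "n_burn", min = 0L)
  thin <- check_count(thin, "thin")
  check_number(seed, "seed")
  if (n_burn >= n_iter) stop_invalid_input("`n_burn` must be < `n_iter`.")
  if ((n_iter - n_burn) %/% thin < 100L) {
    stop_invalid_input("Settings must retain at least 100 draws per chain.")
  }
  if (any(proposal_scales <= 0)) stop_invalid_parameter("Proposal scales must be > 0.")
  structure(
    list(
      n_chains = n_chains, n_iter = n_iter, n_burn = n_burn, thin = thin,
      seed = as.integer(seed), proposal_scales = proposal_scales
    ),
    class = "mcmc_settings"
  )
}

log_dinvgamma <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

#' Log posterior of the Gompertz model in AR(1) form
#'
#' Log prior plus log likelihood, conditioning on the first observation (the
#' likelihood is the product of the Gaussian transition densities, matching
#' the regression formulation of the maximum likelihood problem). Priors:
#' Gamma(1, 1) on the intercept `r`, standard normal on `beta` (untruncated)
#' and InvGamma(0.1, 0.1) on `sigma2`. Outside the prior support
#' (`r <= 0` or `sigma2 <= 0`) the function returns `-Inf` rather than
#' throwing: samplers treat such proposals as rejected.
#'
#' @param series Numeric vector of log abundances (length >= 2).
#' @param intercept,beta,sigma2 Parameter values at which to evaluate.
#' @return The (unnormalised) log posterior density.
#' @export
log_posterior_gompertz <- function(series, intercept, beta, sigma2) {
  y <- if (inherits(series, "pop_trajectory")) trajectory_values(series) else series
  if (length(y) < 2L) stop_invalid_input("`series` must have length >= 2.")
  if (intercept <= 0 || sigma2 <= 0) return(-Inf)
  n <- length(y)
  loglik <- sum(dnorm(y[-1L], intercept + beta * y[-n], sqrt(sigma2), log = TRUE))
  logprior <- dgamma(intercept, shape = 1, rate = 1, log = TRUE) +
    dnorm(beta, 0, 1, log = TRUE) +
    log_dinvgamma(sigma2, 0.1, 0.1)
  loglik + logprior
}

#' Log posterior of the stochastic Ricker model
#'
#' Gaussian likelihood on the per-step log growth rate
#' `log(Y_t / Y_{t-1}) = r (1 - Y_{t-1} / K) + e_t`, conditioning on the
#' first observation. Priors: Gamma(1, 1) on `r` and Gamma(0.1, 0.1) on both
#' `K` and `sigma2`. Returns `-Inf` outside the positive support.
#'
#' @param series Numeric vector of abundances (strictly positive).
#' @param r,K,sigma2 Parameter values at which to evaluate.
#' @return The (unnormalised) log posterior density.
#' @export
log_posterior_ricker <- function(series, r, K, sigma2) {
  Y <- if (inherits(series, "pop_trajectory")) trajectory_values(series) else series
  if (length(Y) < 2L) stop_invalid_input("`series` must have length >= 2.")
  if (any(Y <= 0)) stop_invalid_input("Ricker series must be strictly positive.")
  if (r <= 0 || K <= 0 || sigma2 <= 0) return(-Inf)
  n <- length(Y)
  g <- log(Y[-1L] / Y[-n])
  mu <- r * (1 - Y[-n] / K)
  loglik <- sum(dnorm(g, mu, sqrt(sigma2), log = TRUE))
  logprior <- dgamma(r, 1, rate = 1, log = TRUE) +
    dgamma(K, 0.1, rate = 0.1, log = TRUE) +
    dgamma(sigma2, 0.1, rate = 0.1, log = TRUE)
  loglik + logprior
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance diagnostic. With `m` chains of
#' length `n`, `W` is the mean within-chain variance, `B/n` the variance of
#' the chain means, and the statistic is
#' `sqrt(((n - 1) / n * W + B / n) / W)`. Values near 1 indicate the chains
#' have mixed over the same distribution; values above ~1.1 signal
#' non-convergence.
#'
#' @param chains A list of >= 2 equal-length numeric vectors, or a matrix
#'   with one column per chain.
#' @return The potential scale reduction factor (a single number).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2L) {
    stop_invalid_input("`chains` must contain at least 2 chains.")
  }
  lens <- lengths(chains)
  if (length(unique(lens)) != 1L) stop_invalid_input("Chains must have equal length.")
  n <- lens[[1L]]
  if (n < 10L) stop_invalid_input("Chains must have length >= 10.")
  means <- vapply(chains, mean, numeric(1))
  w <- mean(vapply(chains, var, numeric(1)))
  b_over_n <- var(means)
  if (w == 0) {
    return(if (b_over_n == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

# Effective sample size across chains: per chain n / (1 + 2 * sum of the
# initial positive autocorrelations), summed over chains.
effective_sample_size <- function(chains) {
  sum(vapply(chains, function(x) {
    n <- length(x)
    if (sd(x) == 0) return(n)
    rho <- as.numeric(acf(x, lag.max = min(200L, n - 1L), plot = FALSE)$acf)[-1L]
    pos <- which(rho <= 0.05)
    cut <- if (length(pos)) pos[1L] - 1L else length(rho)
    n / (1 + 2 * sum(rho[seq_len(cut)]))
  }, numeric(1)))
}

summarize_chains <- function(chain_list, term) {
  all_draws <- unlist(chain_list, use.names = FALSE)
  finite <- all_draws[is.finite(all_draws)]
  qs <- quantile(finite, c(0.025, 0.5, 0.975), names = FALSE)
  rhat <- if (all(vapply(chain_list, function(x) all(is.finite(x)), logical(1)))) {
    gelman_rubin(chain_list)
  } else {
    NA_real_
  }
  ess <- if (is.na(rhat)) NA_real_ else effective_sample_size(chain_list)
  tibble::tibble(
    term = term,
    mean = mean(finite), sd = sd(finite),
    q2.5 = qs[1L], median = qs[2L], q97.5 = qs[3L],
    rhat = rhat, ess = ess
  )
}

run_chains <- function(kernel, data, settings, inits, scale_names) {
  scales <- settings$proposal_scales[scale_names]
  if (any(is.na(scales))) {
    stop_invalid_parameter(sprintf(
      "`proposal_scales` must provide entries for: %s.",
      paste(scale_names, collapse = ", ")
    ))
  }
  withr::with_seed(settings$seed, {
    lapply(seq_len(settings$n_chains), function(j) {
      res <- kernel(
        data, settings$n_iter, settings$n_burn, settings$thin,
        inits[[j]], scales
      )
      res$chain <- j
      res
    })
  })
}

build_fit <- function(chain_results, param_names, derived_fun, model, settings,
                      n_obs) {
  n_chains <- length(chain_results)
  # per-parameter list of per-chain draw vectors
  chains_by_param <- lapply(seq_along(param_names), function(p) {
    lapply(chain_results, function(cr) cr$draws[, p])
  })
  names(chains_by_param) <- param_names
  if (!is.null(derived_fun)) {
    chains_by_param <- c(chains_by_param, derived_fun(chains_by_param))
  }
  summary <- purrr::imap_dfr(chains_by_param, function(cl, nm) summarize_chains(cl, nm))
  draws <- purrr::imap_dfr(chains_by_param, function(cl, nm) {
    purrr::imap_dfr(cl, function(x, j) {
      tibble::tibble(chain = j, iter = seq_along(x), parameter = nm, value = x)
    })
  })
  accept <- purrr::map_dfr(chain_results, function(cr) {
    tibble::tibble(
      chain = cr$chain,
      parameter = param_names,
      accept_rate = as.numeric(cr$accept)
    )
  })
  n_nonstationary <- sum(vapply(chain_results, function(cr) cr$n_nonstationary, numeric(1)))
  max_rhat <- max(summary$rhat, na.rm = TRUE)
  if (max_rhat > 1.1) {
    warn(sprintf(
      "Gelman-Rubin statistic above 1.1 (max %.3f): chains may not have converged.",
      max_rhat
    ))
  }
  structure(
    list(
      model = model, summary = summary, draws = draws, accept = accept,
      settings = settings, n_obs = n_obs,
      n_nonstationary = n_nonstationary,
      converged = is.finite(max_rhat) && max_rhat <= 1.1
    ),
    class = c(paste0(model, "_bayes"), "ddvar_bayes")
  )
}

#' Bayesian fit of the Gompertz model in AR(1) form
#'
#' Samples the posterior of (`r`, `beta`, `sigma2`) under the priors of
#' [log_posterior_gompertz()] by Metropolis-within-Gibbs: random-walk
#' Metropolis updates for `r` and `beta` (the Gamma prior on `r` breaks full
#' normal conjugacy) and the conjugate inverse-gamma update for `sigma2`.
#' Chains start from the least-squares estimates, with chain `j` displaced
#' by `j` OLS standard errors in alternating directions so starts are
#' overdispersed. The derived log carrying capacity `k = r / (1 - beta)` is
#' summarised per draw. Draws with `|beta| >= 1` are retained (the prior is
#' untruncated) but counted in `n_nonstationary`, and `k` is undefined
#' (`NA`) for them.
#'
#' @param series Log-abundance series: a numeric vector or a log-scale
#'   [new_trajectory()] (length >= 10).
#' @param settings An [mcmc_settings()] object.
#' @return An object of class `gompertz_bayes` / `ddvar_bayes` with
#'   [tidy()] and [glance()] methods; `$summary` holds posterior mean, sd,
#'   2.5/50/97.5% quantiles, the Gelman-Rubin statistic and effective sample
#'   size per parameter, `$draws` the retained draws in long format.
#' @export
#' @examples
#' p <- gompertz_params(0.4, 1, 0.1)
#' y <- simulate_gompertz(p, n_steps = 100, seed = 1)
#' fit <- fit_gompertz_bayes(y, mcmc_settings(n_iter = 2000, n_burn = 500, seed = 1))
#' tidy(fit)
fit_gompertz_bayes <- function(series, settings = mcmc_settings()) {
  y <- if (inherits(series, "pop_trajectory")) {
    trajectory_values(convert_scale(series, "log"))
  } else {
    series
  }
  if (!is.numeric(y) || length(y) < 10L) {
    stop_invalid_input("`series` must be numeric with length >= 10.")
  }
  stopifnot(inherits(settings, "mcmc_settings"))
  ols <- fit_gompertz_ols(y)
  inits <- lapply(seq_len(settings$n_chains), function(j) {
    dir <- (-1)^j
    c(
      max(ols$intercept + dir * j * ols$se_intercept, 0.01),
      ols$beta + dir * j * ols$se_beta,
      ols$sigma2 * exp(dir * j * 0.5)
    )
  })
  chain_results <- run_chains(
    gompertz_chain_cpp, y, settings, inits, c("r", "beta", "sigma2")
  )
  derived_k <- function(chains_by_param) {
    list(k = purrr::map2(
      chains_by_param$r, chains_by_param$beta,
      function(r, b) ifelse(abs(b) < 1, r / (1 - b), NA_real_)
    ))
  }
  build_fit(chain_results, c("r", "beta", "sigma2"), derived_k,
    "gompertz", settings,
    n_obs = length(y)
  )
}

#' Bayesian fit of the stochastic Ricker model
#'
#' Samples the posterior of (`r`, `K`, `sigma2`) under the priors of
#' [log_posterior_ricker()]. All three parameters are positive and updated
#' by random-walk Metropolis on the log scale. Initial values come from the
#' linearised regression of the per-step log growth rate on abundance, with
#' multiplicative overdispersion across chains.
#'
#' @param series Abundance series on the natural scale: a strictly positive
#'   numeric vector or a [new_trajectory()] (length >= 10; log-scale
#'   trajectories are exponentiated).
#' @inheritParams fit_gompertz_bayes
#' @return An object of class `ricker_bayes` / `ddvar_bayes`.
#' @export
fit_ricker_bayes <- function(series, settings = mcmc_settings()) {
  Y <- if (inherits(series, "pop_trajectory")) {
    trajectory_values(convert_scale(series, "natural"))
  } else {
    series
  }
  if (!is.numeric(Y) || length(Y) < 10L) {
    stop_invalid_input("`series` must be numeric with length >= 10.")
  }
  if (any(!is.finite(Y)) || any(Y <= 0)) {
    stop_invalid_input("Ricker series must be finite and strictly positive.")
  }
  stopifnot(inherits(settings, "mcmc_settings"))
  # linearised start: log(Y_t/Y_{t-1}) = r - (r/K) Y_{t-1} + e
  n <- length(Y)
  g <- log(Y[-1L] / Y[-n])
  x <- Y[-n]
  lin <- lm(g ~ x)
  r0 <- unname(coef(lin)[1L])
  slope <- unname(coef(lin)[2L])
  K0 <- if (is.finite(slope) && slope < 0 && r0 > 0) -r0 / slope else mean(Y)
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.5
  s20 <- max(sum(stats::residuals(lin)^2) / max(n - 3L, 1L), 1e-4)
  inits <- lapply(seq_len(settings$n_chains), function(j) {
    dir <- (-1)^j
    c(r0, K0, s20) * exp(dir * j * 0.25)
  })
  chain_results <- run_chains(
    ricker_chain_cpp, Y, settings, inits, c("r", "K", "sigma2")
  )
  build_fit(chain_results, c("r", "K", "sigma2"), NULL, "ricker", settings,
    n_obs = length(Y)
  )
}

#' @export
print.ddvar_bayes <- function(x, ...) {
  cat(sprintf(
    "<%s_bayes> %d observations, %d chains x %d retained draws%s\n",
    x$model, x$n_obs, x$settings$n_chains,
    (x$settings$n_iter - x$settings$n_burn) %/% x$settings$thin,
    if (x$converged) "" else " [NOT CONVERGED: Rhat > 1.1]"
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ddvar_bayes <- function(x, ...) x$summary

#' @export
glance.ddvar_bayes <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    nobs = x$n_obs,
    n_chains = x$settings$n_chains,
    n_draws = nrow(x$draws) / dplyr::n_distinct(x$draws$parameter),
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    min_ess = min(x$summary$ess, na.rm = TRUE),
    n_nonstationary = x$n_nonstationary,
    converged = x$converged
  )
}

#' Posterior mean of a fitted parameter
#'
#' The package's point estimate is the posterior mean (the median is also
#' reported in summaries).
#'
#' @param fit A `ddvar_bayes` fit.
#' @param parameter Parameter name (e.g. `"sigma2"`).
#' @return The posterior mean as a single number.
#' @export
posterior_mean <- function(fit, parameter) {
  stopifnot(inherits(fit, "ddvar_bayes"))
  row <- fit$summary[fit$summary$term == parameter, ]
  if (nrow(row) != 1L) stop_invalid_input(sprintf("Unknown parameter `%s`.", parameter))
  row$mean
}
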