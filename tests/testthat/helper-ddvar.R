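# Shared fixtures for the test suite. Everything is generated in code under
# fixed seeds; nothing is read from disk.

# Short MCMC budget for tests that exercise mechanics rather than
# convergence quality (determinism, I/O shapes, error paths).
quick_settings <- function(seed = 1L) {
  mcmc_settings(n_chains = 2L, n_iter = 1500L, n_burn = 500L, seed = seed)
}

# Monte-Carlo standard error of the sample variance of a Gaussian AR(1)
# segment of length n: Var(s^2) ~ (2 v_inf^2 / n) (1 + beta^2) / (1 - beta^2).
se_sample_variance_ar1 <- function(beta, sigma2, n) {
  v_inf <- sigma2 / (1 - beta^2)
  sqrt(2 * v_inf^2 / n * (1 + beta^2) / (1 - beta^2))
}

# Standard error of the sample mean of an AR(1) segment.
se_sample_mean_ar1 <- function(beta, sigma2, n) {
  v_inf <- sigma2 / (1 - beta^2)
  sqrt(v_inf / n * (1 + beta) / (1 - beta))
}

design_cell_params <- function(r, sigma2) gompertz_params(r = r, k = 1, sigma2 = sigma2)
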