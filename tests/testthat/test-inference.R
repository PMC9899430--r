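test_that("least-squares fit matches hand-computed regressions", {
  # perfect linear trend: slope exactly 1
  trend <- fit_gompertz_ols(c(1, 2, 3, 4, 5))
  expect_equal(trend$beta, 1)
  expect_equal(trend$intercept, 1)

  # hand least squares on the three pairs {(0,1), (1,0), (0,1)}
  zigzag <- fit_gompertz_ols(c(0, 1, 0, 1))
  expect_equal(zigzag$beta, -1)
  expect_equal(zigzag$intercept, 1)
  expect_equal(zigzag$sigma2, 0)

  expect_error(fit_gompertz_ols(rep(2, 10)), class = "ddvar_degenerate_regression")
  expect_error(fit_gompertz_ols(c(1, 2)), class = "ddvar_invalid_input")
})

test_that("OLS recovers generating parameters on a long series", {
  p <- gompertz_params(0.4, 1, 0.10) # beta = 0.6
  tr <- simulate_gompertz(p, n_steps = 1e4, seed = 21)
  fit <- fit_gompertz_ols(tr)
  expect_lt(abs(fit$beta - 0.6), 3 * fit$se_beta)
  expect_lt(abs(fit$intercept - 0.4), 3 * fit$se_intercept)
  # sigma2 SE ~ sigma2 * sqrt(2/n)
  expect_lt(abs(fit$sigma2 - 0.10), 3 * 0.10 * sqrt(2 / fit$n))
  expect_named(tidy(fit), c("term", "estimate", "std.error"))
  expect_equal(glance(fit)$k, fit$intercept / (1 - fit$beta))
})

test_that("Gompertz log posterior matches an independent density computation", {
  expect_identical(log_posterior_gompertz(c(0.5, 0.7), -0.1, 0.5, 0.1), -Inf)
  expect_identical(log_posterior_gompertz(c(0.5, 0.7), 0.4, 0.5, -0.2), -Inf)

  # two-point series: one transition density plus the three prior densities,
  # assembled here from textbook formulas (inverse-gamma via the gamma
  # density of 1/sigma2 with the change-of-variables factor)
  y <- c(0.8, 1.3)
  r <- 0.4; b <- 0.5; s2 <- 0.15
  lik <- dnorm(y[2], r + b * y[1], sqrt(s2), log = TRUE)
  pri <- dgamma(r, 1, rate = 1, log = TRUE) +
    dnorm(b, log = TRUE) +
    dgamma(1 / s2, 0.1, rate = 0.1, log = TRUE) - 2 * log(s2)
  expect_equal(log_posterior_gompertz(y, r, b, s2), lik + pri, tolerance = 1e-12)

  # zero-residual series: doubling sigma2 lowers the likelihood term by (m/2) log 2
  ar <- ar_form(0.4, 0.5, 0)
  y0 <- 2
  y_det <- deterministic_solution(y0, ar, 0:10)
  m <- length(y_det) - 1
  lp1 <- log_posterior_gompertz(y_det, 0.4, 0.5, 0.1)
  lp2 <- log_posterior_gompertz(y_det, 0.4, 0.5, 0.2)
  prior_diff <- (dgamma(1 / 0.2, 0.1, rate = 0.1, log = TRUE) - 2 * log(0.2)) -
    (dgamma(1 / 0.1, 0.1, rate = 0.1, log = TRUE) - 2 * log(0.1))
  expect_equal(lp2 - lp1 - prior_diff, -(m / 2) * log(2), tolerance = 1e-10)
})

test_that("Ricker log posterior matches an independent density computation", {
  Y <- c(2, 1.5)
  r <- 0.5; K <- 1.8; s2 <- 0.2
  lik <- dnorm(log(Y[2] / Y[1]), r * (1 - Y[1] / K), sqrt(s2), log = TRUE)
  pri <- dgamma(r, 1, rate = 1, log = TRUE) +
    dgamma(K, 0.1, rate = 0.1, log = TRUE) +
    dgamma(s2, 0.1, rate = 0.1, log = TRUE)
  expect_equal(log_posterior_ricker(Y, r, K, s2), lik + pri, tolerance = 1e-12)
  expect_identical(log_posterior_ricker(Y, -1, K, s2), -Inf)
  expect_error(log_posterior_ricker(c(1, -1), r, K, s2), class = "ddvar_invalid_input")
})

test_that("Gelman-Rubin statistic reproduces the between/within formula", {
  withr::with_seed(13, {
    base <- rnorm(100)
    # identical copies: zero between-chain variance
    expect_lte(gelman_rubin(list(base, base, base)), 1 + 1e-9)

    # well mixed: two independent standard normal chains
    expect_lt(gelman_rubin(list(rnorm(1e4), rnorm(1e4))), 1.01)

    # separated chains: offset by 10 sds
    c1 <- rnorm(200)
    c2 <- rnorm(200) + 10
    expect_gt(gelman_rubin(list(c1, c2)), 1.5)

    # direct evaluation of the formula on small fixed chains
    a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
    b <- c(2, 4, 6, 8, 10, 1, 3, 5, 7, 9)
    n <- 10
    w <- mean(c(var(a), var(b)))
    b_over_n <- var(c(mean(a), mean(b)))
    expect_equal(gelman_rubin(list(a, b)), sqrt(((n - 1) / n * w + b_over_n) / w))
  })
  expect_error(gelman_rubin(list(rnorm(20))), class = "ddvar_invalid_input")
  expect_error(gelman_rubin(list(rnorm(20), rnorm(21))), class = "ddvar_invalid_input")
})

test_that("Bayesian fits are pure functions of data, settings and seed", {
  p <- gompertz_params(0.4, 1, 0.10)
  tr <- simulate_gompertz(p, n_steps = 80, seed = 31)
  f1 <- suppressWarnings(fit_gompertz_bayes(tr, quick_settings(seed = 5)))
  f2 <- suppressWarnings(fit_gompertz_bayes(tr, quick_settings(seed = 5)))
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$draws, f2$draws)

  nat <- convert_scale(tr, "natural")
  r1 <- suppressWarnings(fit_ricker_bayes(nat, quick_settings(seed = 6)))
  r2 <- suppressWarnings(fit_ricker_bayes(nat, quick_settings(seed = 6)))
  expect_identical(r1$summary, r2$summary)

  f3 <- suppressWarnings(fit_gompertz_bayes(tr, quick_settings(seed = 7)))
  expect_false(identical(f1$summary, f3$summary))
})

test_that("posterior summaries are well formed", {
  p <- gompertz_params(0.4, 1, 0.10)
  tr <- simulate_gompertz(p, n_steps = 100, seed = 41)
  fit <- fit_gompertz_bayes(tr, mcmc_settings(n_iter = 4000, n_burn = 1000, seed = 2))
  s <- tidy(fit)
  expect_setequal(s$term, c("r", "beta", "sigma2", "k"))
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  expect_true(all(s$sd >= 0))
  # the PSRF sits below 1 by about 1/(2n) when chains agree perfectly
  expect_true(all(s$rhat >= 1 - 1e-3, na.rm = TRUE))
  g <- glance(fit)
  expect_equal(g$nobs, 101)
  expect_equal(g$n_chains, 3)
  expect_error(mcmc_settings(n_iter = 1000, n_burn = 1000), class = "ddvar_invalid_input")
  expect_error(mcmc_settings(n_iter = 150, n_burn = 100), class = "ddvar_invalid_input")
  expect_error(posterior_mean(fit, "nope"), class = "ddvar_invalid_input")
})

test_that("large-sample posterior agrees with truth and with least squares", {
  p <- gompertz_params(0.4, 1, 0.10)
  tr <- simulate_gompertz(p, n_steps = 1e4, seed = 51)
  ols <- fit_gompertz_ols(tr)
  fit <- fit_gompertz_bayes(tr, mcmc_settings(seed = 8))
  s <- tidy(fit)
  for (term in c("r", "beta", "sigma2")) {
    truth <- c(r = 0.4, beta = 0.6, sigma2 = 0.10)[[term]]
    row <- s[s$term == term, ]
    expect_lt(abs(row$mean - truth), 3 * row$sd)
  }
  ols_est <- c(r = ols$intercept, beta = ols$beta, sigma2 = ols$sigma2)
  for (term in names(ols_est)) {
    row <- s[s$term == term, ]
    expect_lt(abs(row$mean - ols_est[[term]]), 0.5 * row$sd)
  }
})

test_that("bias of both estimators shrinks as the series grows", {
  p <- gompertz_params(0.4, 1, 0.10)
  err <- vapply(c(100, 1000, 10000), function(n) {
    per_rep <- vapply(1:8, function(i) {
      tr <- simulate_gompertz(p, n_steps = n, seed = 1000 * i + n %% 97)
      ols <- fit_gompertz_ols(tr)
      bay <- suppressWarnings(fit_gompertz_bayes(tr, quick_settings(seed = i)))
      c(
        ols = abs(ols$beta - 0.6) + abs(ols$sigma2 - 0.10),
        bayes = abs(posterior_mean(bay, "beta") - 0.6) +
          abs(posterior_mean(bay, "sigma2") - 0.10)
      )
    }, numeric(2))
    rowMeans(per_rep)
  }, numeric(2))
  expect_true(all(diff(err["ols", ]) < 0))
  expect_true(all(diff(err["bayes", ]) < 0))
})

test_that("Ricker posterior recovers generating parameters", {
  rp <- ricker_params(0.4, K = exp(1), sigma2 = 0.10)
  tr <- simulate_ricker(rp, n_steps = 500, seed = 61)
  fit <- fit_ricker_bayes(tr, mcmc_settings(seed = 9))
  s <- tidy(fit)
  for (term in c("r", "K", "sigma2")) {
    truth <- c(r = 0.4, K = exp(1), sigma2 = 0.10)[[term]]
    row <- s[s$term == term, ]
    expect_lt(abs(row$mean - truth), 3 * row$sd)
  }
  expect_error(fit_ricker_bayes(c(-1, rep(1, 20)), quick_settings()),
    class = "ddvar_invalid_input"
  )
})
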