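#' Least-squares fit of the Gompertz model in AR(1) form
#'
#' Regresses `y_t` on `y_{t-1}` by ordinary least squares. Because the AR(1)
#' model is linear with Gaussian innovations, these are also the (conditional)
#' maximum likelihood estimates of the intercept `r`, the density-dependence
#' strength `beta`, and the environmental variance `sigma2`. The variance
#' estimate is the residual sum of squares divided by `n - 3`, where `n` is
#' the series length: there are `n - 1` transition pairs and two regression
#' coefficients. Standard errors are the usual regression ones; they ignore
#' the serial dependence of the y's and should be read as rough scales, not
#' valid confidence intervals.
#'
#' @param series Numeric vector of log abundances, length >= 4 and
#'   non-constant (a [new_trajectory()] is accepted and its full value
#'   vector used).
#' @return An object of class `gompertz_ols`: a list with `intercept`,
#'   `beta`, `sigma2`, standard errors, residual degrees of freedom and the
#'   underlying `lm` fit. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' p <- gompertz_params(0.4, 1, 0.1)
#' fit <- fit_gompertz_ols(simulate_gompertz(p, n_steps = 200, seed = 1))
#' tidy(fit)
fit_gompertz_ols <- function(series) {
  y <- if (inherits(series, "pop_trajectory")) trajectory_values(series) else series
  if (!is.numeric(y) || length(y) < 4L) {
    stop_invalid_input("`series` must be a numeric vector of length >= 4.")
  }
  if (!all(is.finite(y))) stop_invalid_input("`series` must be finite throughout.")
  if (sd(y) == 0) {
    abort("`series` is constant: the lag regression is degenerate.",
      class = "ddvar_degenerate_regression"
    )
  }
  n <- length(y)
  y_t <- y[-1L]
  y_lag <- y[-n]
  if (sd(y_lag) == 0) {
    abort("Lagged values are constant: the lag regression is degenerate.",
      class = "ddvar_degenerate_regression"
    )
  }
  fit <- lm(y_t ~ y_lag)
  est <- coef(fit)
  # noiseless series are legal inputs: silence the perfect-fit note, the
  # zero standard errors are exact there
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  df <- n - 3L
  sigma2 <- sum(stats::residuals(fit)^2) / df
  structure(
    list(
      intercept = unname(est[1L]), beta = unname(est[2L]), sigma2 = sigma2,
      se_intercept = unname(se[1L]), se_beta = unname(se[2L]),
      df_residual = df, n = n, lm_fit = fit
    ),
    class = "gompertz_ols"
  )
}

#' @export
print.gompertz_ols <- function(x, ...) {
  cat(sprintf(
    "<gompertz_ols> n = %d: intercept (r) = %.4f (se %.4f), beta = %.4f (se %.4f), sigma2 = %.4f\n",
    x$n, x$intercept, x$se_intercept, x$beta, x$se_beta, x$sigma2
  ))
  invisible(x)
}

#' @export
tidy.gompertz_ols <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "beta", "sigma2"),
    estimate = c(x$intercept, x$beta, x$sigma2),
    std.error = c(x$se_intercept, x$se_beta, NA_real_)
  )
}

#' @export
glance.gompertz_ols <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    df.residual = x$df_residual,
    sigma2 = x$sigma2,
    beta = x$beta,
    k = if (abs(x$beta) < 1) x$intercept / (1 - x$beta) else NA_real_
  )
}
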