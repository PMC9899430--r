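#' Strength of density dependence from Gompertz parameters
#'
#' In the log-scale Gompertz model `y_t = y_{t-1} + r (1 - y_{t-1} / k) + e_t`
#' the autoregressive coefficient of the equivalent AR(1) form
#' `y_t = r + beta y_{t-1} + e_t` is `beta = 1 - r / k`. `beta` measures the
#' strength of density dependence: `beta = 0` (r = k) is white noise around
#' the equilibrium, values approaching 1 mean weak return tendency per step.
#'
#' @param r Intrinsic growth rate per time step (> 0).
#' @param k Natural-log carrying capacity (> 0).
#' @return The autoregressive coefficient `1 - r / k`.
#' @seealso [k_from_rbeta()] for the inverse map.
#' @export
#' @examples
#' beta_from_rk(0.4, 1) # 0.6
beta_from_rk <- function(r, k) {
  check_number(r, "r")
  check_number(k, "k")
  if (r <= 0) stop_invalid_parameter("`r` must be > 0.")
  if (k <= 0) stop_invalid_parameter("`k` must be > 0 (division by k).")
  1 - r / k
}

#' Log carrying capacity from growth rate and density-dependence strength
#'
#' Inverts [beta_from_rk()]: `k = r / (1 - beta)`. Defined only for
#' stationary-compatible `beta < 1`.
#'
#' @param r Intrinsic growth rate (> 0).
#' @param beta Autoregressive coefficient (< 1).
#' @return The log carrying capacity `r / (1 - beta)`.
#' @export
k_from_rbeta <- function(r, beta) {
  check_number(r, "r")
  check_number(beta, "beta")
  if (r <= 0) stop_invalid_parameter("`r` must be > 0.")
  if (beta >= 1) {
    stop_nonstationary("`beta` must be < 1: at beta = 1 the carrying capacity diverges.")
  }
  r / (1 - beta)
}

check_stationary_beta <- function(beta) {
  check_number(beta, "beta")
  if (abs(beta) >= 1) {
    msg <- if (abs(beta) == 1) {
      "|beta| = 1: the process is a random walk (with drift r) and has no stationary distribution; Var(y_t) = t * sigma2 grows without bound."
    } else {
      "|beta| > 1: the process diverges and has no stationary distribution."
    }
    stop_nonstationary(msg)
  }
  invisible(beta)
}

#' Stationary mean of the log-scale Gompertz / AR(1) process
#'
#' For `|beta| < 1` the stationary mean is `mu_inf = intercept / (1 - beta)`,
#' which equals the log carrying capacity `k` of the Gompertz
#' parameterisation and the deterministic equilibrium `y_inf`.
#'
#' @param ar An [ar_form()] object, or a list with `intercept` and `beta`.
#' @return The stationary mean of log abundance.
#' @export
stationary_mean <- function(ar) {
  ar <- as_ar_form(ar)
  check_stationary_beta(ar$beta)
  ar$intercept / (1 - ar$beta)
}

#' Stationary variance of the AR(1) population process
#'
#' `v_inf = sigma2 / (1 - beta^2)`: environmental variance amplified by
#' density feedback. Strictly increasing in `|beta|` at fixed `sigma2`, so
#' stronger density regulation induces larger stationary fluctuations.
#'
#' @param beta Autoregressive coefficient, `|beta| < 1`.
#' @param sigma2 Environmental (innovation) variance, >= 0.
#' @return The stationary variance of log abundance.
#' @export
#' @examples
#' stationary_variance(0.6, 0.10) # 0.15625
stationary_variance <- function(beta, sigma2) {
  check_stationary_beta(beta)
  check_number(sigma2, "sigma2")
  if (sigma2 < 0) stop_invalid_parameter("`sigma2` must be >= 0.")
  sigma2 / (1 - beta^2)
}

#' Density-dependent component of the stationary variance
#'
#' The excess of the stationary variance over the purely environmental
#' variance: `sigma2_dd = beta^2 * sigma2 / (1 - beta^2)`, i.e. the
#' amplification of environmental noise caused by density regulation.
#'
#' @inheritParams stationary_variance
#' @return The density-dependent variance component (>= 0).
#' @export
dd_variance <- function(beta, sigma2) {
  stationary_variance(beta, sigma2) - sigma2
}

#' Proportion of stationary variance due to density regulation
#'
#' `phi_dd = sigma2_dd / v_inf = beta^2`, independent of the environmental
#' variance. This gives the AR(1) coefficient a second biological reading:
#' its square is the share of population variability attributable to density
#' feedback.
#'
#' @param beta Autoregressive coefficient, `|beta| < 1`.
#' @return `beta^2`.
#' @export
dd_proportion <- function(beta) {
  check_stationary_beta(beta)
  beta^2
}

#' Closed-form solution of the deterministic Gompertz recursion
#'
#' The noiseless AR(1) difference equation `y_t = r + beta y_{t-1}` has the
#' closed form `y_t = y_inf + beta^t (y_0 - y_inf)` with
#' `y_inf = r / (1 - beta)`. Convergence to `y_inf` is monotone for
#' `0 < beta < 1` and through damped oscillations for `-1 < beta < 0`.
#'
#' @param y0 Initial log abundance.
#' @param ar An [ar_form()] object (or coercible list).
#' @param t Non-negative integer time (vectorised).
#' @return `y_t` for each requested `t`.
#' @export
deterministic_solution <- function(y0, ar, t) {
  check_number(y0, "y0")
  ar <- as_ar_form(ar)
  check_stationary_beta(ar$beta)
  if (any(t < 0) || any(t != as.integer(t))) {
    stop_invalid_input("`t` must contain non-negative integers.")
  }
  y_inf <- ar$intercept / (1 - ar$beta)
  y_inf + ar$beta^t * (y0 - y_inf)
}

#' Theoretical autocovariance of the stationary AR(1) process
#'
#' `gamma(h) = beta^h * v_inf` for lag `h >= 0`; at `h = 0` this is the
#' stationary variance. Used as the oracle for weak stationarity (the
#' autocovariance depends on the lag only, not on time).
#'
#' @param h Non-negative integer lag (vectorised).
#' @inheritParams stationary_variance
#' @return Autocovariance at each lag.
#' @export
theoretical_autocovariance <- function(h, beta, sigma2) {
  if (any(h < 0) || any(h != as.integer(h))) {
    stop_invalid_input("`h` must contain non-negative integers.")
  }
  beta^h * stationary_variance(beta, sigma2)
}

#' Small-noise stationary log-variance of the Ricker model
#'
#' Linearising the stochastic Ricker map about its carrying capacity gives a
#' log-scale AR(1) process with coefficient `1 - r`, hence approximate
#' stationary log-variance `sigma2 / (1 - (1 - r)^2)`. This is a small-noise
#' approximation, accurate when `sigma2` is small relative to the curvature
#' of the map; it is used as a simulation oracle, never as an exact result.
#'
#' @param r Ricker intrinsic growth rate, in (0, 2) so the linearised
#'   dynamics are stable.
#' @param sigma2 Environmental variance (>= 0).
#' @return Approximate stationary variance of log abundance.
#' @export
ricker_linearized_variance <- function(r, sigma2) {
  check_number(r, "r")
  check_number(sigma2, "sigma2")
  if (r <= 0 || r >= 2) {
    stop_invalid_parameter("Linearisation requires 0 < r < 2 (|1 - r| < 1).")
  }
  if (sigma2 < 0) stop_invalid_parameter("`sigma2` must be >= 0.")
  sigma2 / (1 - (1 - r)^2)
}

#' Analytic stationary summary of a Gompertz / AR(1) parameterisation
#'
#' @param ar An [ar_form()] or [gompertz_params()] object.
#' @return A one-row tibble with `mu_inf` (stationary mean, equal to the log
#'   carrying capacity) and `v_inf` (stationary variance).
#' @export
stationary_summary <- function(ar) {
  ar <- as_ar_form(ar)
  tibble::tibble(
    mu_inf = stationary_mean(ar),
    v_inf = stationary_variance(ar$beta, ar$sigma2)
  )
}

#' Analytic decomposition of the stationary variance
#'
#' Splits `v_inf = sigma2 / (1 - beta^2)` into the environmental variance
#' `sigma2` and the density-dependent excess `sigma2_dd`, with
#' `phi_dd = sigma2_dd / v_inf = beta^2`. The two components sum to `v_inf`
#' exactly.
#'
#' @inheritParams stationary_variance
#' @return A one-row tibble with columns `v_inf`, `sigma2_env`, `sigma2_dd`,
#'   `phi_dd`.
#' @export
#' @examples
#' decompose_analytic(0.6, 0.10)
decompose_analytic <- function(beta, sigma2) {
  v_inf <- stationary_variance(beta, sigma2)
  tibble::tibble(
    v_inf = v_inf,
    sigma2_env = sigma2,
    sigma2_dd = v_inf - sigma2,
    phi_dd = dd_proportion(beta)
  )
}
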