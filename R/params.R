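#' Parameters of the stochastic Gompertz model
#'
#' The discrete-time stochastic Gompertz model on the natural scale is
#' `Y_t = Y_{t-1} exp{ r (1 - ln(Y_{t-1}) / k) + e_t }` with i.i.d. Gaussian
#' shocks `e_t ~ N(0, sigma2)`. On the log scale it is the linear recursion
#' `y_t = y_{t-1} + r (1 - y_{t-1} / k) + e_t`, an AR(1) process with
#' coefficient `beta = 1 - r / k`. Construction checks positivity and warns
#' if the implied `beta` falls outside the stationary region `|beta| < 1`
#' (i.e. r >= 2k).
#'
#' @param r Intrinsic growth rate per time step (> 0); `exp(r)` is the
#'   multiplicative growth rate absent density feedback.
#' @param k Natural-log carrying capacity (> 0); `exp(k)` is the carrying
#'   capacity `K` on the abundance scale.
#' @param sigma2 Environmental variance of the log-scale shocks (>= 0).
#' @return An object of class `gompertz_params` (a named list with `r`, `k`,
#'   `sigma2` and the derived `beta`).
#' @export
#' @examples
#' p <- gompertz_params(r = 0.4, k = 1, sigma2 = 0.10)
#' p$beta # 0.6
gompertz_params <- function(r, k, sigma2) {
  check_number(r, "r")
  check_number(k, "k")
  check_number(sigma2, "sigma2")
  if (r <= 0) stop_invalid_parameter("`r` must be > 0.")
  if (k <= 0) stop_invalid_parameter("`k` must be > 0.")
  if (sigma2 < 0) stop_invalid_parameter("`sigma2` must be >= 0.")
  beta <- beta_from_rk(r, k)
  if (abs(beta) >= 1) {
    warn(sprintf(
      "Implied beta = %.4f is outside (-1, 1): the process has no stationary distribution.",
      beta
    ))
  }
  structure(
    list(r = r, k = k, sigma2 = sigma2, beta = beta),
    class = "gompertz_params"
  )
}

#' Carrying capacity of a Gompertz parameterisation on the abundance scale
#'
#' @param params A [gompertz_params()] object.
#' @return `K = exp(k)`.
#' @export
carrying_capacity <- function(params) {
  stopifnot(inherits(params, "gompertz_params"))
  exp(params$k)
}

#' AR(1) form of the log-scale Gompertz model
#'
#' `y_t = intercept + beta * y_{t-1} + e_t` with `e_t ~ N(0, sigma2)`. The
#' intercept equals the Gompertz growth rate `r`; `beta = 1 - r / k` is the
#' strength of density dependence. The map to [gompertz_params()] is a
#' bijection (`k = r / (1 - beta)`) whenever `beta < 1`.
#'
#' @param intercept AR(1) intercept (the Gompertz `r`).
#' @param beta Autoregressive coefficient; stationary iff `|beta| < 1`.
#' @param sigma2 Innovation (environmental) variance (>= 0).
#' @return An object of class `ar_form`.
#' @export
ar_form <- function(intercept, beta, sigma2) {
  check_number(intercept, "intercept")
  check_number(beta, "beta")
  check_number(sigma2, "sigma2")
  if (sigma2 < 0) stop_invalid_parameter("`sigma2` must be >= 0.")
  structure(
    list(intercept = intercept, beta = beta, sigma2 = sigma2),
    class = "ar_form"
  )
}

#' Coerce to the AR(1) form
#'
#' @param x An `ar_form`, [gompertz_params()], or a named list with fields
#'   `intercept`/`beta`/`sigma2`.
#' @return An `ar_form` object.
#' @export
as_ar_form <- function(x) UseMethod("as_ar_form")

#' @export
as_ar_form.ar_form <- function(x) x

#' @export
as_ar_form.gompertz_params <- function(x) {
  ar_form(intercept = x$r, beta = x$beta, sigma2 = x$sigma2)
}

#' @export
as_ar_form.list <- function(x) {
  if (!all(c("intercept", "beta", "sigma2") %in% names(x))) {
    stop_invalid_input("List must have fields `intercept`, `beta`, `sigma2`.")
  }
  ar_form(x$intercept, x$beta, x$sigma2)
}

#' Gompertz parameterisation of an AR(1) form
#'
#' @param ar An [ar_form()] with `intercept > 0` and `beta < 1`.
#' @return A [gompertz_params()] object with `k = intercept / (1 - beta)`.
#' @export
as_gompertz_params <- function(ar) {
  ar <- as_ar_form(ar)
  gompertz_params(
    r = ar$intercept,
    k = k_from_rbeta(ar$intercept, ar$beta),
    sigma2 = ar$sigma2
  )
}

#' Parameters of the stochastic Ricker model
#'
#' `Y_t = Y_{t-1} exp{ r (1 - Y_{t-1} / K) + e_t }` with Gaussian shocks on
#' the log growth rate. Unlike the Gompertz model, the density feedback acts
#' on the untransformed abundance, and no closed-form stationary variance
#' decomposition exists; see [ricker_linearized_variance()] for the
#' small-noise approximation. `r`, `K` and `sigma2` here are the Ricker
#' model's own parameters, distinct from the Gompertz ones.
#'
#' @param r Intrinsic growth rate (> 0).
#' @param K Carrying capacity on the abundance (untransformed) scale (> 0).
#' @param sigma2 Environmental variance (>= 0).
#' @return An object of class `ricker_params`.
#' @export
ricker_params <- function(r, K, sigma2) {
  check_number(r, "r")
  check_number(K, "K")
  check_number(sigma2, "sigma2")
  if (r <= 0) stop_invalid_parameter("`r` must be > 0.")
  if (K <= 0) stop_invalid_parameter("`K` must be > 0.")
  if (sigma2 < 0) stop_invalid_parameter("`sigma2` must be >= 0.")
  structure(list(r = r, K = K, sigma2 = sigma2), class = "ricker_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf(
    "<gompertz_params> r = %g, k = %g, sigma2 = %g (beta = %g)\n",
    x$r, x$k, x$sigma2, x$beta
  ))
  invisible(x)
}

#' @export
print.ricker_params <- function(x, ...) {
  cat(sprintf("<ricker_params> r = %g, K = %g, sigma2 = %g\n", x$r, x$K, x$sigma2))
  invisible(x)
}

#' @export
print.ar_form <- function(x, ...) {
  cat(sprintf(
    "<ar_form> intercept = %g, beta = %g, sigma2 = %g%s\n",
    x$intercept, x$beta, x$sigma2,
    if (abs(x$beta) < 1) " (stationary)" else " (non-stationary)"
  ))
  invisible(x)
}
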