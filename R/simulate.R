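#' Simulate the stochastic Gompertz model on the log scale
#'
#' Iterates `y_t = y_{t-1} + r (1 - y_{t-1} / k) + e_t` with
#' `e_t ~ N(0, sigma2)` i.i.d. Simulation is done directly on the log scale,
#' where the model is linear, avoiding exp/log round-trip error. With
#' `sigma2 = 0` the output equals the deterministic recursion exactly, and a
#' given seed reproduces the trajectory bit for bit.
#'
#' @param params A [gompertz_params()] object.
#' @param y0 Initial log abundance (finite). Defaults to the equilibrium
#'   `k`, so the trajectory starts at the stationary mean.
#' @param n_steps Number of post-initial steps to simulate (>= 1).
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @param n_discard Leading steps to flag as transient (default 0).
#' @return A log-scale [new_trajectory()] of `n_steps + 1` values.
#' @export
#' @examples
#' p <- gompertz_params(r = 0.4, k = 1, sigma2 = 0.10)
#' traj <- simulate_gompertz(p, n_steps = 300, seed = 1, n_discard = 200)
#' length(stationary_segment(traj)) # 100
simulate_gompertz <- function(params, y0 = params$k, n_steps, seed,
                              n_discard = 0L) {
  stopifnot(inherits(params, "gompertz_params"))
  check_number(y0, "y0")
  n_steps <- check_count(n_steps, "n_steps")
  check_number(seed, "seed")
  ar <- as_ar_form(params)
  values <- numeric(n_steps + 1L)
  values[1L] <- y0
  eps <- if (params$sigma2 > 0) {
    withr::with_seed(as.integer(seed), rnorm(n_steps, 0, sqrt(params$sigma2)))
  } else {
    numeric(n_steps)
  }
  for (t in seq_len(n_steps)) {
    values[t + 1L] <- ar$intercept + ar$beta * values[t] + eps[t]
  }
  new_trajectory(values,
    scale = "log", n_discard = n_discard,
    seed = as.integer(seed), source = "gompertz", params = params
  )
}

#' Simulate the stochastic Ricker model
#'
#' Iterates `Y_t = Y_{t-1} exp{ r (1 - Y_{t-1} / K) + e_t }` with
#' `e_t ~ N(0, sigma2)` on the natural abundance scale. With `sigma2 = 0`
#' and `Y0 = K` the trajectory stays at the carrying capacity. A trajectory
#' that underflows to zero (possible only at very large noise levels) aborts
#' with a diagnostic rather than continuing silently.
#'
#' @param params A [ricker_params()] object.
#' @param Y0 Initial abundance (> 0). Defaults to the carrying capacity `K`.
#' @inheritParams simulate_gompertz
#' @return A natural-scale [new_trajectory()].
#' @export
simulate_ricker <- function(params, Y0 = params$K, n_steps, seed,
                            n_discard = 0L) {
  stopifnot(inherits(params, "ricker_params"))
  check_number(Y0, "Y0")
  if (Y0 <= 0) stop_invalid_input("`Y0` must be > 0.")
  n_steps <- check_count(n_steps, "n_steps")
  check_number(seed, "seed")
  values <- numeric(n_steps + 1L)
  values[1L] <- Y0
  eps <- if (params$sigma2 > 0) {
    withr::with_seed(as.integer(seed), rnorm(n_steps, 0, sqrt(params$sigma2)))
  } else {
    numeric(n_steps)
  }
  for (t in seq_len(n_steps)) {
    prev <- values[t]
    values[t + 1L] <- prev * exp(params$r * (1 - prev / params$K) + eps[t])
    if (values[t + 1L] <= 0 || !is.finite(values[t + 1L])) {
      abort(
        sprintf(
          "Ricker trajectory left the positive abundance range at step %d (value %g); the model is not meaningful in this regime.",
          t, values[t + 1L]
        ),
        class = "ddvar_numerical_failure"
      )
    }
  }
  new_trajectory(values,
    scale = "natural", n_discard = n_discard,
    seed = as.integer(seed), source = "ricker", params = params
  )
}

#' Generate a replicated ensemble of trajectories
#'
#' Simulates `n_replicates` independent trajectories from the requested
#' model. Replicate `i` uses seed `base_seed + i`, so ensembles are fully
#' reproducible and each replicate can be regenerated in isolation. The
#' initial value is the equilibrium on the model's own scale (the log
#' carrying capacity `k` for Gompertz, `K` for Ricker), and `n_discard`
#' leading steps are flagged transient on every replicate.
#'
#' @param model `"gompertz"` or `"ricker"`.
#' @param params Matching parameter object ([gompertz_params()] or
#'   [ricker_params()]).
#' @param n_replicates Number of trajectories (>= 1).
#' @param n_steps Post-initial steps per trajectory.
#' @param n_discard Leading transient steps flagged on each trajectory
#'   (must be < `n_steps`).
#' @param base_seed Integer seed from which per-replicate seeds are derived.
#' @return A list of [new_trajectory()] objects of length `n_replicates`.
#' @export
generate_ensemble <- function(model = c("gompertz", "ricker"), params,
                              n_replicates, n_steps, n_discard, base_seed) {
  model <- match.arg(model)
  n_replicates <- check_count(n_replicates, "n_replicates")
  n_steps <- check_count(n_steps, "n_steps")
  n_discard <- check_count(n_discard, "n_discard", min = 0L)
  if (n_discard >= n_steps) {
    stop_invalid_input("`n_discard` must be < `n_steps` so a stationary segment remains.")
  }
  check_number(base_seed, "base_seed")
  sim_one <- function(i) {
    seed_i <- as.integer(base_seed) + i
    if (model == "gompertz") {
      simulate_gompertz(params, n_steps = n_steps, seed = seed_i, n_discard = n_discard)
    } else {
      simulate_ricker(params, n_steps = n_steps, seed = seed_i, n_discard = n_discard)
    }
  }
  purrr::map(seq_len(n_replicates), sim_one)
}

#' Bind an ensemble of trajectories into one long tibble
#'
#' @param ensemble A list of trajectories from [generate_ensemble()].
#' @return A tibble with columns `replicate`, `t`, `value`, `scale`,
#'   `discard_flag` (TRUE for the initial value and transient steps).
#' @export
ensemble_tbl <- function(ensemble) {
  purrr::imap_dfr(ensemble, function(traj, i) {
    tibble::tibble(
      replicate = i,
      t = traj$t,
      value = traj$value,
      scale = attr(traj, "scale"),
      discard_flag = traj$t <= attr(traj, "n_discard")
    )
  })
}
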