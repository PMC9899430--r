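test_that("noiseless Gompertz reproduces the deterministic recursion exactly", {
  # start at equilibrium, no noise: fixed point
  at_eq <- simulate_gompertz(gompertz_params(0.4, 1, 0), y0 = 1, n_steps = 10, seed = 1)
  expect_equal(trajectory_values(at_eq), rep(1, 11))

  # hand-iterated closed form y_t = 1 + 0.5^t (2 - 1)
  tr <- simulate_gompertz(gompertz_params(0.5, 1, 0), y0 = 2, n_steps = 3, seed = 1)
  expect_equal(trajectory_values(tr), c(2, 1.5, 1.25, 1.125))

  # closed form agrees at every step, including damped oscillation (beta < 0)
  for (p in list(gompertz_params(0.5, 1, 0), gompertz_params(1.5, 1, 0))) {
    tr <- simulate_gompertz(p, y0 = 3, n_steps = 50, seed = 1)
    closed <- deterministic_solution(3, as_ar_form(p), 0:50)
    expect_lt(max(abs(trajectory_values(tr) - closed)), 1e-12)
  }
})

test_that("noiseless convergence is monotone for beta > 0 and oscillating for beta < 0", {
  up <- simulate_gompertz(gompertz_params(0.3, 1, 0), y0 = 0.2, n_steps = 30, seed = 1)
  dev_up <- trajectory_values(up) - 1
  expect_true(all(diff(abs(dev_up)) < 0))
  expect_true(all(dev_up < 0)) # approaches k from below, never overshoots

  osc <- simulate_gompertz(gompertz_params(1.6, 1, 0), y0 = 2, n_steps = 20, seed = 1)
  dev <- trajectory_values(osc) - 1
  expect_true(all(dev[-1] * dev[-length(dev)] < 0)) # sign alternates each step
  expect_true(all(diff(abs(dev)) < 0))
})

test_that("simulation is deterministic in the seed and validates inputs", {
  p <- gompertz_params(0.6, 1, 0.2)
  a <- simulate_gompertz(p, n_steps = 50, seed = 99)
  b <- simulate_gompertz(p, n_steps = 50, seed = 99)
  c <- simulate_gompertz(p, n_steps = 50, seed = 100)
  expect_identical(trajectory_values(a), trajectory_values(b))
  expect_false(identical(trajectory_values(a), trajectory_values(c)))
  expect_equal(attr(a, "y0"), p$k) # default start at the log carrying capacity

  expect_error(simulate_gompertz(p, y0 = Inf, n_steps = 5, seed = 1),
    class = "ddvar_invalid_input"
  )
  expect_error(gompertz_params(0.4, 1, -0.1), class = "ddvar_invalid_parameter")
  expect_error(simulate_gompertz(p, n_steps = 0, seed = 1), class = "ddvar_invalid_input")

  rp <- ricker_params(0.5, 2, 0.05)
  ra <- simulate_ricker(rp, n_steps = 50, seed = 7)
  rb <- simulate_ricker(rp, n_steps = 50, seed = 7)
  expect_identical(trajectory_values(ra), trajectory_values(rb))
  expect_error(simulate_ricker(rp, Y0 = 0, n_steps = 5, seed = 1),
    class = "ddvar_invalid_input"
  )
})

test_that("long-run Gompertz moments match the stationary formulas", {
  p <- gompertz_params(0.2, 0.4, 0.1) # beta = 0.5, mu_inf = 0.4
  n <- 1e5
  tr <- simulate_gompertz(p, n_steps = n, seed = 2, n_discard = 1000L)
  seg <- stationary_segment(tr)
  m <- length(seg)
  expect_lt(
    abs(mean(seg) - stationary_mean(as_ar_form(p))),
    3 * se_sample_mean_ar1(p$beta, p$sigma2, m)
  )
  expect_lt(
    abs(var(seg) - stationary_variance(p$beta, p$sigma2)),
    3 * se_sample_variance_ar1(p$beta, p$sigma2, m)
  )
})

test_that("lag-h autocorrelation of a stationary segment is close to beta^h", {
  p <- gompertz_params(0.4, 1, 0.1) # beta = 0.6
  tr <- simulate_gompertz(p, n_steps = 1e5, seed = 3, n_discard = 1000L)
  seg <- stationary_segment(tr)
  rho <- as.numeric(acf(seg, lag.max = 3, plot = FALSE)$acf)[-1]
  theory <- theoretical_autocovariance(1:3, p$beta, p$sigma2) /
    theoretical_autocovariance(0L, p$beta, p$sigma2)
  expect_lt(max(abs(rho - theory)), 0.02)
})

test_that("Ricker equilibrium, single step and small-noise limit behave", {
  eq <- simulate_ricker(ricker_params(0.4, 10, 0), Y0 = 10, n_steps = 5, seed = 1)
  expect_equal(trajectory_values(eq), rep(10, 6))

  one <- simulate_ricker(ricker_params(0.5, 1, 0), Y0 = 2, n_steps = 1, seed = 1)
  expect_equal(trajectory_values(one)[2], 2 * exp(-0.5))

  tr <- simulate_ricker(ricker_params(0.4, 1, 0.001), n_steps = 1e5, seed = 4,
    n_discard = 1000L
  )
  v <- var(log(stationary_segment(tr)))
  expect_lt(abs(v - ricker_linearized_variance(0.4, 0.001)) / ricker_linearized_variance(0.4, 0.001), 0.05)
})

test_that("Ricker trajectories that leave the positive range abort loudly", {
  # enormous noise drives the abundance to overflow/underflow within a few steps
  expect_error(
    simulate_ricker(ricker_params(0.5, 1, 4e5), n_steps = 200, seed = 1),
    class = "ddvar_numerical_failure"
  )
})

test_that("ensembles derive per-replicate seeds and record bookkeeping", {
  p <- design_cell_params(r = 0.8, sigma2 = 0.10)
  ens <- generate_ensemble("gompertz", p,
    n_replicates = 100, n_steps = 300,
    n_discard = 200, base_seed = 1
  )
  expect_length(ens, 100)
  expect_true(all(vapply(ens, function(tr) length(stationary_segment(tr)), numeric(1)) == 100))
  expect_true(all(vapply(ens, function(tr) attr(tr, "y0"), numeric(1)) == p$k))

  single <- generate_ensemble("gompertz", p, 1, 50, 10, base_seed = 7)
  expect_identical(
    trajectory_values(single[[1]]),
    trajectory_values(simulate_gompertz(p, n_steps = 50, seed = 8, n_discard = 10))
  )

  again <- generate_ensemble("gompertz", p, 5, 50, 10, base_seed = 3)
  again2 <- generate_ensemble("gompertz", p, 5, 50, 10, base_seed = 3)
  expect_identical(
    lapply(again, trajectory_values),
    lapply(again2, trajectory_values)
  )

  expect_error(generate_ensemble("gompertz", p, 0, 50, 10, 1), class = "ddvar_invalid_input")
  expect_error(generate_ensemble("gompertz", p, 2, 50, 50, 1), class = "ddvar_invalid_input")
})

test_that("stationary_segment drops exactly the initial value and transient", {
  p <- design_cell_params(0.8, 0.10)
  tr <- simulate_gompertz(p, n_steps = 300, seed = 5, n_discard = 200L)
  expect_length(stationary_segment(tr), 100)
  expect_identical(stationary_segment(tr), trajectory_values(tr)[202:301])

  no_discard <- simulate_gompertz(p, n_steps = 20, seed = 5)
  expect_length(stationary_segment(no_discard), 20)

  flat <- simulate_gompertz(gompertz_params(0.4, 1, 0), y0 = 1, n_steps = 10, seed = 1)
  expect_equal(var(stationary_segment(flat)), 0)

  all_transient <- new_trajectory(rep(1, 6), n_discard = 5L)
  expect_error(stationary_segment(all_transient), class = "ddvar_invalid_input")
})

test_that("trajectories validate their invariants and convert scales", {
  expect_error(new_trajectory(c(1, NA, 2)), class = "ddvar_invalid_input")
  expect_error(new_trajectory(c(1, -1, 2), scale = "natural"), class = "ddvar_invalid_input")
  expect_error(new_trajectory(rep(1, 5), n_discard = 10), class = "ddvar_invalid_input")

  p <- design_cell_params(0.8, 0.10)
  tr <- simulate_gompertz(p, n_steps = 30, seed = 1, n_discard = 10)
  nat <- convert_scale(tr, "natural")
  expect_equal(trajectory_values(nat), exp(trajectory_values(tr)))
  back <- convert_scale(nat, "log")
  expect_equal(trajectory_values(back), trajectory_values(tr))
  expect_equal(attr(nat, "n_discard"), 10L)
  expect_equal(nrow(tr), 31L) # tibble rows: initial value plus each step
})
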