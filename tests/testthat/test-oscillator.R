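# Internal oscillator: gradient perception, phase modulation, helical
# reference trajectory.

test_that("perceived gradient normalizes by the distance grown", {
  expect_equal(perceived_gradient(0.505, 0.5, dt = 0.1, G_avr = 1), 0.05)
  expect_equal(perceived_gradient(0.5, 0.5, 0.1, 1), 0)
  expect_lt(perceived_gradient(0.49, 0.5, 0.1, 1), 0)
  expect_error(perceived_gradient(1, 0, 0.1, 0), "positive")
})

test_that("phase modulation accelerates up-gradient, symmetric limits", {
  osc <- oscillator_state(T_s = pi)
  # uniform field: increment exactly dt * T_s (sign(0) = 0)
  o1 <- oscillator_step(osc, 0, dt = 0.1)
  expect_equal(o1$t_s, 0.1 * pi, tolerance = 1e-15)
  expect_equal(o1$s_s, sin(0.1 * pi))
  # near-zero gradient: multiplier 1.5 up, 0.5 down
  up <- oscillator_step(osc, 1e-12, dt = 0.1)
  dn <- oscillator_step(osc, -1e-12, dt = 0.1)
  expect_equal(up$t_s, 0.1 * pi * 1.5, tolerance = 1e-9)
  expect_equal(dn$t_s, 0.1 * pi * 0.5, tolerance = 1e-9)
  # large gradients: multiplier returns to 1 (sign-dominated sensing)
  big <- oscillator_step(osc, 50, dt = 0.1)
  expect_equal(big$t_s, 0.1 * pi, tolerance = 1e-6)
  expect_error(oscillator_state(T_s = -1), "positive")
})

test_that("uniform field keeps the oscillation period at P", {
  env <- root_environment(field = resource_field("uniform", C0 = 0.5))
  for (P in c(1, 5, 10)) {
    sim <- simulate_root(duration = 30, dim = 2, orientation = "vertical",
                         w_s = 1, v_s = 5, P = P, peak_d = 3, env = env,
                         osc_emission = "alternating")
    m <- nutation_metrics(sim)
    expect_equal(m$median_period, P, tolerance = 0.1 / P + 1e-9)
  }
})

test_that("rotating emission halves the one-side period by the beat", {
  env <- root_environment(field = resource_field("uniform", C0 = 0.5))
  sim <- simulate_root(duration = 30, dim = 2, orientation = "vertical",
                       w_s = 1, v_s = 5, P = 5, peak_d = 3, env = env,
                       osc_emission = "rotating")
  expect_equal(nutation_metrics(sim)$median_period, 2.5, tolerance = 0.05)
})

test_that("the scripted rotating excitation grows a helical path", {
  turn_period <- function(rate, w = 0.1, dur = 40) {
    sim <- helical_reference_run(duration = dur,
                                 phi_fun = function(t) pi / 2 + rate * t,
                                 w = w)
    tr <- sim$trace
    late <- tr$t > dur / 2             # after the lock-in transient
    xr <- stats::residuals(stats::lm(tr$x[late] ~ tr$t[late]))
    yr <- stats::residuals(stats::lm(tr$y[late] ~ tr$t[late]))
    rad <- sqrt(xr^2 + yr^2)
    # the tip loops around a drifting axis with bounded radius ...
    expect_gt(mean(rad), 0.2)
    expect_lt(max(rad), 2.5 * mean(rad))
    # ... with near-constant vertical advance
    fit <- stats::lm(tr$z[late] ~ tr$t[late])
    expect_lt(max(abs(stats::residuals(fit))),
              0.05 * abs(diff(range(tr$z[late]))))
    # turn period from the unwrapped phase of the projection
    ang <- atan2(yr, xr)
    dphi <- diff(ang)
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    2 * pi / abs(sum(dphi) / (length(dphi) * 0.1))
  }
  p1 <- turn_period(2 * pi / 10)
  expect_equal(p1, 10, tolerance = 0.1)
  # doubling the rotation frequency halves the turn period
  p2 <- turn_period(2 * pi / 5)
  expect_equal(p2, 5, tolerance = 0.1)
})

test_that("zero oscillator weight grows straight", {
  env <- linear_field_env()
  sim <- simulate_root(duration = 10, dim = 2, orientation = "vertical",
                       w_s = 0, env = env)
  expect_lt(diff(range(sim$trace$x)), 1e-9)
  expect_equal(utils::tail(sim$trace$z, 1), -10, tolerance = 1e-6)
})

test_that("up-gradient klinotaxis climbs in the showcase configuration", {
  env <- linear_field_env()
  sim <- simulate_root(duration = 30, dim = 3, orientation = "vertical",
                       w_s = 1, v_s = 5, T_s = 0.75 * pi, peak_d = 3,
                       env = env)
  expect_gt(utils::tail(sim$trace$x, 1), 0)
  expect_gt(utils::tail(sim$trace$C, 1), 0.5)
})
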