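# Signal network: baseline zonation surface, finite-speed stimulus
# propagation, and the leaky aggregation.

test_that("baseline surface is a normalized Gaussian over the zone", {
  d <- seq(6, 0.1, by = -0.1)
  g <- baseline_surface(d, peak_d = 3, zone_length = 6, G_base = 1)
  # summed elongation rate over the zone equals the baseline rate
  expect_equal(sum(g), 1, tolerance = 1e-9)
  # profile maximum at the zonation peak
  expect_equal(d[which.max(g)], 3)
  # moving the peak moves the maximal-bending region correspondingly
  g15 <- baseline_surface(d, peak_d = 1.5)
  expect_equal(d[which.max(g15)], 1.5)
  expect_error(baseline_surface(d, peak_d = 7), "zone")
})

test_that("stimulus propagation is causal pure advection", {
  st <- stimulus_field("gravity", velocity = 5, weight = 0.5)
  for (t in seq(0, 2, by = 0.1))
    st <- emit_stimulus(st, t, 1, 0)     # constant unit source at phi = 0
  # before arrival the surface is zero
  expect_equal(propagate(st, t = 0.5, d = 3, phi = 0), 0)
  # arrival at d = 3 takes 0.6 h; after that the full strength is seen
  expect_equal(propagate(st, t = 1, d = 3, phi = 0), 1)
  # antisymmetric circumferential profile
  for (ph in c(0, 0.7, 2)) {
    expect_equal(propagate(st, 1, 1, ph + pi), -propagate(st, 1, 1, ph),
                 tolerance = 1e-12)
  }
  # profile crosses zero a quarter-turn from the peak
  expect_equal(propagate(st, 1, 1, pi / 2), 0, tolerance = 1e-12)
  expect_equal(propagate(st, 1, 1, -pi / 2), 0, tolerance = 1e-12)
})

test_that("advection preserves the source shape along the zone", {
  st <- stimulus_field("resource", velocity = 2, weight = 1)
  tg <- seq(0, 10, by = 0.1)
  for (t in tg) st <- emit_stimulus(st, t, sin(2 * pi * t / 3), 0)
  # S(t, d) = S(t - delta, d - v * delta) on aligned grids
  for (dd in c(0.4, 1.0, 2.0)) {
    delta <- dd / 2                 # time to traverse dd at v = 2
    expect_equal(propagate(st, 8, 3, 0),
                 propagate(st, 8 - delta, 3 - dd, 0), tolerance = 1e-9)
  }
})

test_that("a pulse history interpolates linearly between samples", {
  st <- stimulus_field("touch", velocity = 1, weight = 1)
  st <- emit_stimulus(st, 0, 0, 0)
  st <- emit_stimulus(st, 1, 1, 0)
  st <- emit_stimulus(st, 2, 0, 0)
  # halfway between emission samples
  expect_equal(propagate(st, 1.5, 1, 0), 0.5)
  expect_equal(propagate(st, 2.5, 1, 0), 0.5)
})

test_that("leaky aggregation has the exact geometric relaxation", {
  # instantaneous update with tau = dt and no stimuli: S_a = bias
  s1 <- aggregate_step(matrix(0.3, 2, 2), list(), numeric(0), b = 1,
                       tau = 0.1, dt = 0.1)
  expect_equal(s1, matrix(1, 2, 2))
  # constant drive u, constant tau: closed-form geometric decay
  u <- 0.8; tau <- 2; dt <- 0.1; s0 <- 0.2
  s <- s0
  for (k in 1:50) s <- aggregate_step(s, list(u - 1), 1, b = 1,
                                      tau = tau, dt = dt)
  t <- 50 * dt
  expect_equal(s, u + (s0 - u) * (1 - dt / tau)^(t / dt),
               tolerance = 1e-12)
  expect_error(aggregate_step(1, list(), numeric(0), 1, tau = 0.05,
                              dt = 0.1), "tau")
})

test_that("Euler aggregation converges first-order to the exponential", {
  # relaxation from 0 toward 1 with tau = 1 h, compared at t = 1 h
  target <- 1 - exp(-1)
  err <- sapply(c(0.1, 0.05, 0.025), function(dt) {
    s <- 0
    for (k in seq_len(round(1 / dt)))
      s <- aggregate_step(s, list(), numeric(0), b = 1, tau = 1, dt = dt)
    abs((1 - s) - exp(-1))
  })
  # halving dt roughly halves the deviation
  expect_gt(err[1] / err[2], 1.7)
  expect_lt(err[1] / err[2], 2.3)
  expect_gt(err[2] / err[3], 1.7)
  expect_lt(err[2] / err[3], 2.3)
})

test_that("net inhibition is floored at zero growth", {
  s <- aggregate_step(1, list(-3), 1, b = 1, tau = 0.1, dt = 0.1)
  expect_equal(s, 0)
})

test_that("strengths outside [-1, 1] are rejected at emission", {
  st <- stimulus_field("gravity", 5, 0.5)
  expect_error(emit_stimulus(st, 0, 1.2, 0), "\\[-1, 1\\]")
})
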