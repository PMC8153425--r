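# Touch sensing, contact geometry, passive correction, and the
# inhibitory-signal memory.

test_that("touch angle decreases away from the apex in both forms", {
  # head-on limit
  expect_equal(touch_angle(0), pi / 2)
  expect_equal(touch_angle(0, method = "power"), pi / 2)
  # compact power-law form at the cylinder radius
  expect_equal(touch_angle(0.5, p_cap = 0.4, method = "power"),
               atan(0.4 * 0.5^(-0.6)), tolerance = 1e-12)
  expect_equal(touch_angle(0.5, p_cap = 0.4, method = "power"), 0.5450,
               tolerance = 1e-3)
  # monotone decreasing in the contact radius
  for (mth in c("profile", "power"))
    expect_gt(touch_angle(0.2, method = mth),
              touch_angle(0.5, method = mth))
  expect_error(touch_angle(-1), "non-negative")
})

test_that("profile touch angle equals the cap-profile slope", {
  # finite-difference oracle on the cap profile r(d)
  for (d in c(0.2, 0.6, 1.2)) {
    h <- 1e-6
    slope <- (cap_radius(d + h) - cap_radius(d - h)) / (2 * h)
    r <- cap_radius(d)
    expect_equal(touch_angle(r), atan(slope), tolerance = 1e-5)
  }
})

test_that("sensory points cover the cap at the surface radius", {
  r <- root_state()
  sp <- sensory_points(r)
  expect_true(all(sp$d <= 1.5))
  # every point lies at the cap radius from the centerline of its ring
  # (default vertical root: the center at arc d sits straight above the tip)
  for (i in seq_along(sp$d)) {
    cen <- tip_position(r) + c(0, 0, sp$d[i])
    expect_equal(sqrt(sum((sp$points[i, ] - cen)^2)),
                 cap_radius(sp$d[i]), tolerance = 1e-9)
  }
})

test_that("contact detection finds the intersected-point summary", {
  # root fully above the floor: no contact
  r <- root_state(origin = c(0, 0, 8))    # tip at z = 2
  expect_null(detect_contact(r, floor_env()$obstacles))
  # tip just crossing the floor: head-on apex contact
  r2 <- root_state(origin = c(0, 0, 5.95))  # tip at z = -0.05
  ev <- detect_contact(r2, floor_env()$obstacles)
  expect_s3_class(ev, "touch_event")
  expect_lt(ev$d_t, 0.3)
  expect_gt(ev$alpha_t, 1.2)              # close to pi/2
  expect_lt(ev$s_t, -0.75)
  # oblique contact on one flank: a vertical wall at x = 0.3 touches the
  # flank whose sensory points extend toward +x
  wall <- obstacle_plane(point = c(0.45, 0, 0), normal = c(-1, 0, 0))
  r3 <- root_state(origin = c(0, 0, 6))    # vertical, tip at origin
  ev3 <- detect_contact(r3, list(wall))
  expect_s3_class(ev3, "touch_event")
  # the mean point sits on the +x flank; with reference y = +x the
  # circumferential angle is near 0
  expect_lt(abs(ev3$phi_t), pi / 4)
})

test_that("passive correction clears penetration without overshoot", {
  obstacles <- floor_env()$obstacles
  # non-intersecting root is untouched
  r <- root_state(origin = c(0, 0, 8))
  r1 <- passive_correction(r, obstacles)
  expect_identical(attr(r1, "iterations"), 0L)
  expect_equal(r1$centers, r$centers)
  # tip pressed 0.05 D below the floor is freed
  r2 <- root_state(origin = c(0, 0, 5.95))
  r3 <- passive_correction(r2, obstacles)
  expect_false(attr(r3, "trapped"))
  sp <- sensory_points(r3)
  expect_gte(min(signed_clearance(obstacles[[1L]], sp$points)), -1e-9)
  # the base never moves
  expect_equal(r3$centers[1L, ], r2$centers[1L, ])
})

test_that("touch memory rises and decays with its time constants", {
  dt <- 0.1
  ev <- structure(list(s_t = -1), class = "touch_event")
  # immediate regime: full inhibition in one step
  expect_equal(touch_signal_step(0, ev, dt, dt, dt), -1)
  # slow decay: geometric relaxation toward zero after contact loss
  s <- -1
  for (k in 1:10) s <- touch_signal_step(s, NULL, dt, dt, tau_decay = 10)
  expect_equal(s, -(1 - 0.1 / 10)^10, tolerance = 1e-12)
  expect_equal(s, -0.9044, tolerance = 1e-4)
  # never touched: stays at zero
  expect_equal(touch_signal_step(0, NULL, dt, dt, 10), 0)
  expect_error(touch_signal_step(0, NULL, dt, tau_rise = 0.01), "tau")
})

test_that("no sensory point rests inside an obstacle after any step", {
  env <- floor_env()
  sim <- simulate_root(duration = 10, dim = 3, orientation = "vertical",
                       origin = c(0, 0, 8), w_g = 0.5, w_t = 0.5,
                       peak_d = 1.5, env = env)
  sp <- sensory_points(sim$root)
  expect_gte(min(signed_clearance(env$obstacles[[1L]], sp$points)), -1e-9)
})

test_that("sliding angle increases with gravitropic dominance", {
  angles <- sapply(c(0.1, 0.5, 0.9), function(wg) {
    run_obstacle_interplay(w_g = wg, w_t = 1 - wg, duration = 12)$steady_angle
  })
  expect_true(all(diff(angles) > 0))
})

test_that("slow touch decay with weak gravitropism cycles contact", {
  s <- run_obstacle_interplay(w_g = 0.1, w_t = 0.9, tau_decay = 10,
                              duration = 16)
  expect_gte(s$contact_losses, 2L)
})
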