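# Cross-section chain kinematics: cap profile, bend construction, chain
# growth, and elongation-zone resampling.

test_that("cap radius follows the power-law taper and saturates", {
  # beyond the cap the radius is half the diameter
  expect_equal(cap_radius(2.0, d_cap = 1.5, p_cap = 0.4, D = 1), 0.5)
  # the very tip has zero radius
  expect_equal(cap_radius(0), 0)
  # mid-cap value: 0.5 * 0.5^0.4
  expect_equal(cap_radius(0.75, 1.5, 0.4, 1), 0.5 * 0.5^0.4,
               tolerance = 1e-12)
  expect_equal(cap_radius(0.75, 1.5, 0.4, 1), 0.37895, tolerance = 1e-4)
  # continuity at the cap boundary
  expect_equal(cap_radius(1.5 - 1e-12), cap_radius(1.5), tolerance = 1e-9)
  expect_error(cap_radius(-0.1), "non-negative")
  expect_error(cap_radius(1, p_cap = 1.2), "p_cap")
})

test_that("bend geometry from flank rates matches the arc relations", {
  b <- bend_from_rates(1.2, 0.8, dt = 0.1, D = 1)
  expect_equal(b$theta, 0.04)
  expect_equal(b$R_c, 2.5)
  expect_equal(b$G_avr, 1.0)
  # equal rates: straight growth, infinite curvature radius
  b0 <- bend_from_rates(1, 1, dt = 0.1, D = 1)
  expect_equal(b0$theta, 0)
  expect_identical(b0$R_c, Inf)
  # arc length of the increment equals R_c * theta = G_avr * dt
  expect_equal(b$R_c * b$theta, b$G_avr * b$dt, tolerance = 1e-12)
  expect_error(bend_from_rates(0.5, 0.8, 0.1), "G_left")
})

test_that("advancing a section bends away from the fast flank", {
  sec <- list(center = c(0, 0, 0), frame = diag(3))
  # zero bend: pure axial translation, frame unchanged
  b0 <- bend_from_rates(1, 1, dt = 0.1)
  s2 <- advance_section(sec, b0)
  expect_equal(s2$center, c(0, 0, 0.1))
  expect_equal(s2$frame, diag(3))
  # fast flank at phi = 0 (local +y): displacement toward -y
  b <- bend_from_rates(1.2, 0.8, dt = 0.1, phi = 0)
  s3 <- advance_section(sec, b)
  expect_lt(s3$center[2L], 0)
  expect_equal(s3$center[1L], 0)
  # mirror: the same bend at phi = pi displaces toward +y symmetric
  bm <- bend_from_rates(1.2, 0.8, dt = 0.1, phi = pi)
  s4 <- advance_section(sec, bm)
  expect_equal(s4$center[2L], -s3$center[2L], tolerance = 1e-12)
  expect_equal(s4$center[3L], s3$center[3L], tolerance = 1e-12)
  expect_error(advance_section(list(center = c(0, 0, 0),
                                    frame = matrix(1, 3, 3)), b),
               "orthonormal")
})

test_that("repeated constant bends trace a circle of radius R_c", {
  b <- bend_from_rates(1.2, 0.8, dt = 0.1, phi = 0)
  sec <- list(center = c(0, 0, 0), frame = diag(3))
  pts <- matrix(0, 200, 3)
  for (i in 1:200) {
    sec <- advance_section(sec, b)
    pts[i, ] <- sec$center
  }
  # analytic circle: center at (0, -R_c, 0), radius R_c, in the yz plane
  r <- sqrt((pts[, 2L] + b$R_c)^2 + pts[, 3L]^2)
  expect_lt(max(abs(r - b$R_c)), 1e-6)
  expect_equal(max(abs(pts[, 1L])), 0)
})

test_that("initial discretization gives n = zone / (dt * G) sections", {
  r <- root_state()
  expect_identical(r$n, 60L)
  expect_equal(nrow(r$centers), 61L)
  seg <- diff(r$centers)
  expect_equal(sqrt(rowSums(seg^2)), rep(0.1, 60), tolerance = 1e-12)
  r2 <- root_state(zone_length = 3)
  expect_identical(r2$n, 30L)
})

test_that("uniform growth extends straight and conserves the zone", {
  gb <- default_gb()
  r <- horizontal_root()
  for (s in 1:50) {
    r <- grow_step(r, gb, gb, rep(0, 60), 0.1)
    expect_equal(attr(r, "extension"), 0.1, tolerance = 1e-9)
    r <- resample_root(r)
  }
  # straight line: no lateral deviation at all
  expect_equal(max(abs(r$centers[, 2L])), 0)
  expect_equal(max(abs(r$centers[, 3L])), 0)
  expect_equal(tip_position(r)[1L], 11, tolerance = 1e-9)
  # zone arc length conserved exactly
  expect_equal(sum(sqrt(rowSums(diff(r$centers)^2))), 6, tolerance = 1e-9)
  # frozen mature trace accumulated one cross-section per step
  expect_identical(nrow(r$mature$centers), 50L)
})

test_that("mature trace is append-only and frozen", {
  gb <- default_gb()
  r <- horizontal_root()
  for (s in 1:10) r <- resample_root(grow_step(r, gb * 1.1, gb * 0.9,
                                               rep(0, 60), 0.1))
  snapshot <- r$mature$centers
  for (s in 1:10) r <- resample_root(grow_step(r, gb * 1.1, gb * 0.9,
                                               rep(0, 60), 0.1))
  expect_identical(r$mature$centers[seq_len(nrow(snapshot)), ], snapshot)
})

test_that("compiled kernel reproduces the reference R path", {
  set.seed(7)
  gb <- default_gb()
  r_ref <- horizontal_root()
  r_cpp <- horizontal_root()
  for (s in 1:40) {
    mod <- 1 + 0.4 * sin(0.3 * s + seq(0, 2, length.out = 60))
    gl <- pmax(gb * mod, gb * (2 - mod))
    gr <- pmin(gb * mod, gb * (2 - mod))
    ph <- runif(60, -pi, pi)
    r_ref <- resample_root(grow_step(r_ref, gl, gr, ph, 0.1))
    r_cpp <- step_root(r_cpp, gl, gr, ph, 0.1)
  }
  expect_equal(r_cpp$centers, r_ref$centers, tolerance = 1e-10)
  expect_equal(r_cpp$frames, r_ref$frames, tolerance = 1e-10)
  expect_equal(r_cpp$mature$centers, r_ref$mature$centers,
               tolerance = 1e-10)
})

test_that("frames stay orthonormal over 1000 bent steps", {
  gb <- default_gb()
  r <- horizontal_root()
  for (s in 1:1000) r <- step_root(r, gb * 1.2, gb * 0.8, rep(0, 60), 0.1)
  expect_lt(max_frame_defect(r), 1e-9)
  # zone length still conserved (along-polyline construction)
  expect_equal(sum(sqrt(rowSums(diff(r$centers)^2))), 6, tolerance = 1e-3)
})

test_that("2-D mode keeps every center in the initial plane", {
  gb <- default_gb()
  r <- horizontal_root()   # plane y = 0: reference is +z, bend axis +/- y
  set.seed(1)
  for (s in 1:200) {
    ph <- sample(c(0, pi), 60, replace = TRUE)
    r <- step_root(r, gb * 1.3, gb * 0.7, ph, 0.1)
  }
  tp <- rbind(r$mature$centers, r$centers)
  expect_lt(max(abs(tp[, 2L])), 1e-9)
})

test_that("self-collision reporting flags loops but not straight roots", {
  gb <- default_gb()
  r <- horizontal_root()
  for (s in 1:100) r <- step_root(r, gb, gb, rep(0, 60), 0.1)
  expect_false(self_collision(r)$collided)
  # strong constant bending curls the root onto itself
  r2 <- horizontal_root()
  for (s in 1:300) r2 <- step_root(r2, gb * 1.8, gb * 0.2, rep(0, 60), 0.1)
  sc <- self_collision(r2)
  expect_true(is.finite(sc$min_distance))
  expect_true(sc$collided)
})
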