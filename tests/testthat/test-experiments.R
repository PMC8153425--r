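# Scripted experiments: determinism, sweep structure, study plumbing,
# multi-root scenario, and trace export.

test_that("identical scenario and seed reproduce traces bit-identically", {
  env <- linear_field_env()
  s1 <- simulate_root(duration = 8, dim = 2, orientation = "vertical",
                      w_s = 0.7, v_s = 4, T_s = pi, peak_d = 2.5,
                      env = env)
  s2 <- simulate_root(duration = 8, dim = 2, orientation = "vertical",
                      w_s = 0.7, v_s = 4, T_s = pi, peak_d = 2.5,
                      env = env)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$root$centers, s2$root$centers)
  g1 <- run_gradient_study(n_runs = 4, duration = 6, seed = 11)
  g2 <- run_gradient_study(n_runs = 4, duration = 6, seed = 11)
  expect_identical(g1$runs, g2$runs)
})

test_that("the gravitropic sweep summarizes runs and groups", {
  sw <- run_gravitropic_sweep(v_g_grid = c(1, 5), w_g_grid = c(0.1, 1.0),
                              duration = 8)
  expect_identical(nrow(sw$runs), 8L)
  # weak sensitivity rows show no circumnutation cycles
  expect_true(all(sw$runs$n_cycles[sw$runs$w_g == 0.1] == 0))
  expect_true(is.finite(sw$amplitude_ratio))
  expect_s3_class(sw$rank_test, "htest")
  expect_output(print(sw), "amplitude ratio")
})

test_that("the gradient study ranks groups consistently", {
  gs <- run_gradient_study(n_runs = 12, duration = 10, seed = 3)
  expect_identical(nrow(gs$runs), 12L)
  expect_true(all(gs$runs$f >= -1 & gs$runs$f <= 1))
  g <- gs$groups
  expect_gte(g["best_5"], g["best_25"])
  expect_gte(g["best_25"], g["all"])
  expect_gte(g["all"], g["worst_25"])
  expect_gte(g["worst_25"], g["worst_5"])
  expect_lte(gs$n_cycling, 12L)
  expect_output(print(gs), "1 circumnutation cycle")
})

test_that("root types specialize by their sensitivities", {
  sp <- run_specialization(duration = 6)
  crown <- sp$sims$crown$trace
  # negative gravitropism: the crown tip ends above its start
  expect_gt(utils::tail(crown$z, 1), crown$z[1])
  # the other roots grow downward
  expect_lt(utils::tail(sp$sims$primary$trace$z, 1),
            sp$sims$primary$trace$z[1])
  # nobody leaves the walled arena
  for (nm in names(sp$sims)) {
    pts <- rbind(sp$sims[[nm]]$root$mature$centers,
                 sp$sims[[nm]]$root$centers)
    expect_true(all(abs(pts[, 1L]) <= 8 + 1e-6))
    expect_true(all(abs(pts[, 2L]) <= 8 + 1e-6))
  }
})

test_that("trace and snapshot exports are well formed", {
  sim <- simulate_root(duration = 4, dim = 2, orientation = "vertical",
                       w_s = 0.5, env = linear_field_env())
  f1 <- tempfile(fileext = ".csv")
  out <- write_root_snapshot(sim, f1)
  expect_true(file.exists(f1))
  got <- utils::read.csv(f1)
  expect_true(all(c("t", "section_index", "d", "cx", "cy", "cz",
                    "radius") %in% names(got)))
  expect_identical(ncol(got), 7L + 9L)
  f2 <- tempfile(fileext = ".csv")
  write_tip_trajectory(sim, f2)
  expect_identical(names(utils::read.csv(f2)), c("t", "x", "y", "z"))
  f3 <- tempfile(fileext = ".csv")
  write_metrics_csv(list(a = sim), f3)
  m <- utils::read.csv(f3)
  expect_true(all(c("run_id", "n_cycles", "median_period",
                    "median_amplitude") %in% names(m)))
  simc <- run_obstacle_interplay(w_g = 0.5, w_t = 0.5, duration = 6)
  fc <- tempfile(fileext = ".csv")
  log <- write_contact_log(simc, fc)
  expect_identical(names(log), c("t", "d_t", "phi_t", "alpha_t", "s_t"))
  expect_gt(nrow(log), 0L)
  unlink(fc)
  f4 <- tempfile(fileext = ".obj")
  export_obj(sim, f4, n_circ = 8)
  lines <- readLines(f4, n = 5)
  expect_true(any(grepl("^v ", lines)))
  unlink(c(f1, f2, f3, f4))
})

test_that("surface recording dumps the long format", {
  sim <- simulate_root(duration = 1, dim = 2, orientation = "vertical",
                       w_s = 0.5, env = linear_field_env(),
                       record_surfaces = TRUE)
  f <- tempfile(fileext = ".csv")
  n <- write_surface_dump(sim, f)
  got <- utils::read.csv(f)
  expect_identical(names(got), c("t", "d", "phi", "G_b", "S_a", "G_s"))
  expect_identical(nrow(got), as.integer(n))
  unlink(f)
})
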