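# Scripted experiments: the gravitropic parameter sweep, root-obstacle
# interplay, the randomized gradient-climbing study, and the multi-root
# specialization scenario.

#' Gravitropic parameter sweep
#'
#' Runs horizontally initialized roots under gravitropic stimulation for
#' every combination of signal speed `v_g`, sensitivity `w_g`, and
#' zonation peak, and quantifies convergence and circumnutation per run.
#' Per-step differential elongation-rate amplitudes (the maximum over the
#' zone of `G_s` at the fastest flank minus the opposite flank) are pooled
#' per zonation-peak group; the ratio of group medians measures how a more
#' distal growth zone amplifies differential growth, and a rank-sum test
#' compares the two groups.
#'
#' @param v_g_grid,w_g_grid Signal-speed (D/hour) and sensitivity grids.
#' @param peaks Zonation-peak distances (units of D), within the common
#'   6 D elongation zone.
#' @param duration Run length (hours, default 16).
#' @param dt,dim,... Passed to [simulate_root()].
#' @return An object of class `gravitropic_sweep`: `runs` (one row per
#'   run: parameters, cycle count, median period/amplitude, final tip
#'   angle), `amp_samples` (pooled per-step differential amplitudes per
#'   peak group), `amplitude_ratio` (ratio of group medians, larger peak
#'   over smaller), and `rank_test` (Wilcoxon rank-sum result).
#' @export
run_gravitropic_sweep <- function(v_g_grid = c(1, 5, 25),
                                  w_g_grid = c(0.1, 0.5, 1.0),
                                  peaks = c(1.5, 3.0),
                                  duration = 16, dt = 0.1, dim = 3, ...) {
  grid <- expand.grid(v_g = v_g_grid, w_g = w_g_grid, peak_d = peaks)
  runs <- cbind(grid, n_cycles = NA_integer_, median_period = NA_real_,
                median_amplitude = NA_real_, final_angle = NA_real_)
  amp_samples <- stats::setNames(
    lapply(peaks, function(p) numeric(0)), paste0("peak_", peaks))
  sims <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sim <- simulate_root(duration = duration, dt = dt, dim = dim,
                         orientation = "horizontal",
                         w_g = grid$w_g[i], v_g = grid$v_g[i],
                         peak_d = grid$peak_d[i], ...)
    m <- nutation_metrics(sim)
    runs$n_cycles[i] <- m$n_cycles
    runs$median_period[i] <- m$median_period
    runs$median_amplitude[i] <- m$median_amplitude
    runs$final_angle[i] <- utils::tail(sim$trace$tip_angle, 1L)
    gkey <- paste0("peak_", grid$peak_d[i])
    amp_samples[[gkey]] <- c(amp_samples[[gkey]], sim$trace$diff_amp)
    sims[[i]] <- sim
  }
  ratio <- NA_real_
  rank_test <- NULL
  if (length(peaks) == 2L) {
    hi <- amp_samples[[which.max(peaks)]]
    lo <- amp_samples[[which.min(peaks)]]
    ratio <- stats::median(hi) / stats::median(lo)
    rank_test <- stats::wilcox.test(hi, lo)
  }
  structure(list(runs = runs, amp_samples = amp_samples,
                 amplitude_ratio = ratio, rank_test = rank_test,
                 sims = sims),
            class = "gravitropic_sweep")
}

#' Root-obstacle interplay run
#'
#' A vertically growing root meets a horizontal plane below its starting
#' position; gravitropic and thigmotropic signals then compete while the
#' tip slides along the surface.  The steady sliding angle is the mean
#' tip-to-obstacle angle over the later part of the contact phase.
#'
#' @param w_g,w_t Gravitropic and thigmotropic sensitivities.
#' @param tau_decay Touch-signal decay constant (hours); `dt` for the
#'   immediate-update regime, 10 for the slow-decay memory regime (the
#'   rise is always immediate).
#' @param duration Run length (hours).
#' @param gap Initial tip height above the plane (units of D).
#' @param dt,dim,... Passed to [simulate_root()].
#' @return A `root_sim` with extra fields: `steady_angle` (degrees),
#'   `contact_losses` (number of contact -> no-contact transitions after
#'   first touch), and `first_contact` (hours).
#' @export
run_obstacle_interplay <- function(w_g = 0.5, w_t = 0.5, tau_decay = dt,
                                   duration = 16, gap = 2, dt = 0.1,
                                   dim = 3, ...) {
  env <- root_environment(
    obstacles = list(obstacle_plane(point = c(0, 0, 0),
                                    normal = c(0, 0, 1))))
  sim <- simulate_root(duration = duration, dt = dt, dim = dim,
                       orientation = "vertical", origin = c(0, 0, 6 + gap),
                       w_g = w_g, w_t = w_t, tau_rise = dt,
                       tau_decay = tau_decay, peak_d = 1.5, env = env, ...)
  tr <- sim$trace
  ic <- which(tr$contact > 0)
  if (length(ic)) {
    t0 <- tr$t[ic[1L]]
    sim$first_contact <- t0
    sel <- tr$t >= t0 + 0.5 * (max(tr$t) - t0)    # post-transient half
    sim$steady_angle <- mean(tr$obstacle_angle[sel], na.rm = TRUE)
    after <- tr$contact[tr$t >= t0]
    sim$contact_losses <- sum(diff(after) < 0)
  } else {
    sim$first_contact <- NA_real_
    sim$steady_angle <- NA_real_
    sim$contact_losses <- 0L
  }
  sim
}

#' Randomized gradient-climbing study
#'
#' `n_runs` two-dimensional simulations of vertically started roots in a
#' linear horizontal resource gradient (slope 0.05 per D, clipped to
#' `[0, 1]`, concentration 0.5 at the starting tip position).  Each root's
#' oscillatory apparatus is parametrized by independent uniform draws:
#' sensitivity `w_s ~ U[0, 1]`, signal speed `v_s ~ U[0, 10]` D/hour,
#' frequency `T_s ~ U[0, 2 pi]` rad/hour, and zonation peak
#' `d ~ U[0.5, 5.5]` D.  After `duration` hours the gradient-climbing
#' performance `f` and the circumnutation metrics are computed per run.
#'
#' @param n_runs Number of randomized runs (default 1000).
#' @param duration Hours per run (default 30).
#' @param seed RNG seed for the parameter draws (the individual
#'   simulations are deterministic).
#' @param dt Time step.
#' @param slope Gradient slope (1/D).
#' @param ... Passed to [simulate_root()].
#' @return An object of class `gradient_study`: `runs` (a data frame with
#'   the draws, `f`, `n_cycles`, `median_period`, `median_amplitude`),
#'   `groups` (median `f` of the best 5%, best 25%, worst 25%, worst 5%,
#'   and all runs), and `n_cycling` (runs with at least one full cycle).
#' @export
run_gradient_study <- function(n_runs = 1000, duration = 30, seed = 1,
                               dt = 0.1, slope = 0.05, ...) {
  set.seed(seed)
  draws <- data.frame(w_s = stats::runif(n_runs),
                      v_s = stats::runif(n_runs, 0, 10),
                      T_s = stats::runif(n_runs, 0, 2 * pi),
                      peak_d = stats::runif(n_runs, 0.5, 5.5))
  env <- root_environment(
    field = resource_field("linear", C0 = 0.5, slope = slope,
                           origin = c(0, 0, 0), direction = c(1, 0, 0)))
  f <- n_cycles <- med_p <- med_a <- rep(NA_real_, n_runs)
  C_start <- concentration(env$field, c(0, 0, 0))
  C_best <- best_concentration(env$field, c(0, 0, 0), duration)
  for (i in seq_len(n_runs)) {
    sim <- simulate_root(duration = duration, dt = dt, dim = 2,
                         orientation = "vertical", origin = c(0, 0, 6),
                         w_s = draws$w_s[i], v_s = draws$v_s[i],
                         T_s = draws$T_s[i], peak_d = draws$peak_d[i],
                         env = env, ...)
    C_end <- utils::tail(sim$trace$C, 1L)
    f[i] <- performance_f(C_start, C_end, C_best)
    m <- nutation_metrics(sim)
    n_cycles[i] <- m$n_cycles
    med_p[i] <- m$median_period
    med_a[i] <- m$median_amplitude
  }
  runs <- cbind(draws, f = f, n_cycles = n_cycles,
                median_period = med_p, median_amplitude = med_a)
  ord <- order(f, decreasing = TRUE)
  top <- function(k) stats::median(f[ord[seq_len(k)]])
  bot <- function(k) stats::median(f[rev(ord)[seq_len(k)]])
  k05 <- max(1L, round(0.05 * n_runs))
  k25 <- max(1L, round(0.25 * n_runs))
  groups <- c(best_5 = top(k05), best_25 = top(k25),
              worst_25 = bot(k25), worst_5 = bot(k05),
              all = stats::median(f))
  structure(list(runs = runs, groups = groups,
                 n_cycling = sum(n_cycles >= 1), seed = seed,
                 C_start = C_start, C_best = C_best),
            class = "gradient_study")
}

#' Multi-root specialization scenario
#'
#' Four differently parametrized root types grow simultaneously in a
#' walled 3-D arena with a radial resource field peaking at the arena
#' center: crown roots (negative gravitropism, `w_g = -1`), primary roots
#' (strongly gravitropic), seminal roots (strongly resource-driven), and
#' lateral roots (mixed).  All roots avoid the walls and each other
#' (capsule-chain contact); each runs the identical model with its own
#' sensitivities.
#'
#' @param duration Hours (default 30).
#' @param dt Time step.
#' @param root_types Data frame with columns `name`, `w_g`, `w_s`, `w_t`
#'   (defaults follow the four root types above).
#' @param seed_positions 4 x 3 matrix of seed (base) positions.
#' @param arena Half-width of the square arena (units of D); walls and
#'   floor are planes, the resource peak sits mid-depth at the center.
#' @param ... Passed to [simulate_root()].
#' @return A list of class `specialization_run`: per-root `root_sim`
#'   results (named by root type) plus the shared `env`.
#' @export
run_specialization <- function(duration = 30, dt = 0.1,
                               root_types = NULL, seed_positions = NULL,
                               arena = 8, ...) {
  if (is.null(root_types))
    root_types <- data.frame(
      name = c("crown", "primary", "seminal", "lateral"),
      w_g = c(-1, 0.95, 0.05, 0.7),
      w_s = c(0, 0.05, 0.95, 0.3),
      w_t = c(0.2, 0.2, 0.2, 0.2))
  k <- nrow(root_types)
  if (is.null(seed_positions))
    seed_positions <- cbind(c(-2, 2, -2, 2)[seq_len(k)],
                            c(-2, -2, 2, 2)[seq_len(k)],
                            rep(-7, k))
  depth <- 2 * arena
  env <- root_environment(
    field = resource_field("radial", center = c(0, 0, -1.5 * arena),
                           Cmax = 1, slope = 0.05),
    obstacles = list(
      obstacle_plane(c(0, 0, -depth), c(0, 0, 1)),     # floor
      obstacle_plane(c(0, 0, 2), c(0, 0, -1)),         # ceiling
      obstacle_plane(c(-arena, 0, 0), c(1, 0, 0)),
      obstacle_plane(c(arena, 0, 0), c(-1, 0, 0)),
      obstacle_plane(c(0, -arena, 0), c(0, 1, 0)),
      obstacle_plane(c(0, arena, 0), c(0, -1, 0))))
  states <- vector("list", k)
  for (i in seq_len(k)) {
    orient <- if (root_types$w_g[i] < 0) c(0, 0, 1) else c(0, 0, -1)
    states[[i]] <- sim_init(
      duration = duration, dt = dt, dim = 3, orientation = orient,
      origin = seed_positions[i, ], peak_d = 3, zone_length = 6,
      G_base = 1, D = 1, d_cap = 1.5, p_cap = 0.4,
      w_g = root_types$w_g[i], v_g = 5, w_t = root_types$w_t[i], v_t = 5,
      tau_rise = dt, tau_decay = dt, w_s = root_types$w_s[i], v_s = 5,
      T_s = pi, P = NULL, phase_locked = FALSE,
      osc_emission = "rotating", env = env, n_phi = 181L,
      bias = 1, tau = dt, extra_stimulus = NULL, record_surfaces = FALSE,
      sensors_ring = 12L, sensors_axial = 6L, correction_step = 2e-3,
      correction_max_iter = 500L, contact_tol = 0)
  }
  n_steps <- states[[1L]]$n_steps
  for (s in seq_len(n_steps)) {
    chains <- lapply(states, function(st)
      obstacle_chain(root_polyline(st$root, every = 3L), radius = 0.5))
    for (i in seq_len(k))
      states[[i]] <- sim_step(states[[i]],
                              extra_obstacles = chains[-i])
  }
  sims <- lapply(states, sim_finalize)
  names(sims) <- root_types$name
  structure(list(sims = sims, env = env, root_types = root_types),
            class = "specialization_run")
}

# Full polyline of a root (mature trace + active zone), optionally thinned.
root_polyline <- function(root, every = 1L) {
  pts <- rbind(root$mature$centers, root$centers)
  if (every > 1L && nrow(pts) > 2L) {
    keep <- unique(c(seq(1L, nrow(pts), by = every), nrow(pts)))
    pts <- pts[keep, , drop = FALSE]
  }
  pts
}

#' Helical reference run
#'
#' A vertically started root driven by a scripted tip excitation of
#' constant strength whose emission angle sweeps the circumference
#' (`phi(t) = pi/2 + pi * t / 10` by default): the rotating differential
#' growth produces a 3-D helical trajectory with stationary horizontal
#' radius and constant vertical advance per turn.
#'
#' @param duration Hours (default 10).
#' @param phi_fun Emission angle as a function of time.
#' @param strength Constant excitation strength.
#' @param w,v Weight and propagation speed of the scripted stimulus.
#' @param ... Passed to [simulate_root()].
#' @return A `root_sim`.
#' @export
helical_reference_run <- function(duration = 10,
                                  phi_fun = function(t) pi / 2 + pi * t / 10,
                                  strength = 1, w = 0.5, v = 5, ...) {
  simulate_root(duration = duration, dim = 3, orientation = "vertical",
                extra_stimulus = list(
                  fun = function(t) list(s = strength, phi = phi_fun(t)),
                  w = w, v = v), ...)
}
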