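# Main simulation loop: couples the section-chain kinematics with the
# signal network, the stimulus generators (gravity, touch, internal
# oscillator), obstacle handling, and per-step trace recording.

#' Simulate the growth of a single root
#'
#' Runs the differential-growth model for `duration` hours: at every step
#' the active stimuli emit signal samples at the tip, propagate axially
#' along the elongation zone at their finite speeds, are aggregated into
#' the signal response surface `S_a` by the leaky network update, and the
#' resulting stimuli growth surface `G_s = G_b * S_a` drives the
#' extend-and-bend kinematics of the section chain.  With obstacles
#' present, contact is detected through cap sensory points, the passive
#' minimal-bending correction keeps the root from penetrating, and the
#' inhibitory touch signal is emitted with the configured rise/decay
#' memory.
#'
#' @param duration Simulated time (hours).
#' @param dt Time step (hours, default 0.1).
#' @param dim 2 or 3.  In 2-D the circumferential grid is restricted to
#'   `phi` in `{0, pi}` and all motion stays in the plane spanned by the
#'   initial axis and the reference direction.
#' @param orientation `"vertical"` (downward), `"horizontal"`, or a unit
#'   3-vector for the initial growth direction.
#' @param origin Base position of the initial root (the tip starts one
#'   zone length away along `orientation`).
#' @param peak_d Zonation peak distance from the tip (units of D).
#' @param zone_length,G_base,D Elongation-zone length, baseline zone-total
#'   growth rate, and root diameter.
#' @param d_cap,p_cap Root-cap geometry (see [cap_radius()]).
#' @param w_g,v_g Gravitropic sensitivity and signal speed (D/hour);
#'   `w_g = 0` disables the stimulus, negative values invert it
#'   (negative gravitropism).
#' @param w_t,v_t Thigmotropic sensitivity and signal speed.
#' @param tau_rise,tau_decay Touch-signal memory constants (hours;
#'   `dt` = immediate).
#' @param w_s,v_s Resource-oscillator sensitivity and signal speed.
#' @param T_s Oscillator angular frequency (rad/hour); alternatively give
#'   the period `P` (hours).
#' @param P Oscillator baseline period (used if `T_s` is missing).
#' @param phase_locked Whether the rotating emission angle follows the
#'   modulated phase (see [oscillator_state()]).
#' @param osc_emission `"rotating"` (default): the oscillator emits
#'   `sin(t_s)` at the circumferential angle `pi + T_s t`, which sweeps
#'   the circumference; `"alternating"`: emission is fixed at `phi = 0`
#'   so the antisymmetric profile alternates the excited flank with the
#'   sign of `sin(t_s)`.  With a uniform resource field the one-side
#'   growth rate oscillates with period `P` under `"alternating"` and
#'   `P/2` under `"rotating"` (the strength and angle beat).
#' @param env A [root_environment()] (gravity, obstacles, resource field).
#' @param n_phi Circumferential grid resolution in 3-D (default 361
#'   samples over `[-pi, pi]`; the two endpoints alias the same angle).
#' @param bias,tau Network bias and decay field (scalars; `tau = dt`
#'   reproduces the instantaneous update used throughout the experiments).
#' @param extra_stimulus Optional scripted stimulus: a list with elements
#'   `fun(t)` returning `list(s, phi)`, plus `w` and `v`.
#' @param record_surfaces If `TRUE`, keep the full `(d, phi)` surfaces
#'   `S_a`, `G_s` at every step (memory heavy; for visualization).
#' @param sensors_ring,sensors_axial Sensory-point layout on the cap.
#' @param correction_step,correction_max_iter Passive-correction bend
#'   step (radians per iteration; see [passive_correction()]) and
#'   iteration cap.
#' @param contact_tol Extra clearance below which a sensory point counts
#'   as touching for signal generation (units of D; default 0, i.e. strict
#'   intersection of the just-grown root, which is what the passive
#'   correction subsequently removes).
#' @return An object of class `root_sim`: list with the final `root`
#'   state, the per-step `trace` (a data frame: time, tip position, tip
#'   angle to gravity, tip concentration, one-side normalized growth rate,
#'   differential-growth amplitude, contact state, obstacle angle, emitted
#'   signals), the `params`, and the `env`.
#' @export
simulate_root <- function(duration = 16, dt = 0.1, dim = 3,
                          orientation = "vertical", origin = NULL,
                          peak_d = 3, zone_length = 6, G_base = 1, D = 1,
                          d_cap = 1.5, p_cap = 0.4,
                          w_g = 0, v_g = 5,
                          w_t = 0, v_t = v_g,
                          tau_rise = dt, tau_decay = dt,
                          w_s = 0, v_s = 5, T_s = NULL, P = 10,
                          phase_locked = FALSE,
                          osc_emission = c("rotating", "alternating"),
                          env = root_environment(),
                          n_phi = 361L, bias = 1, tau = dt,
                          extra_stimulus = NULL,
                          record_surfaces = FALSE,
                          sensors_ring = 16L, sensors_axial = 8L,
                          correction_step = 2e-3,
                          correction_max_iter = 500L,
                          contact_tol = 0) {
  st <- sim_init(duration = duration, dt = dt, dim = dim,
                 orientation = orientation, origin = origin,
                 peak_d = peak_d, zone_length = zone_length,
                 G_base = G_base, D = D, d_cap = d_cap, p_cap = p_cap,
                 w_g = w_g, v_g = v_g, w_t = w_t, v_t = v_t,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 w_s = w_s, v_s = v_s, T_s = T_s, P = P,
                 phase_locked = phase_locked,
                 osc_emission = match.arg(osc_emission),
                 env = env, n_phi = n_phi,
                 bias = bias, tau = tau, extra_stimulus = extra_stimulus,
                 record_surfaces = record_surfaces,
                 sensors_ring = sensors_ring, sensors_axial = sensors_axial,
                 correction_step = correction_step,
                 correction_max_iter = correction_max_iter,
                 contact_tol = contact_tol)
  for (k in seq_len(st$n_steps)) st <- sim_step(st)
  sim_finalize(st)
}

# ---- internal machinery -------------------------------------------------

sim_init <- function(duration, dt, dim, orientation, origin, peak_d,
                     zone_length, G_base, D, d_cap, p_cap, w_g, v_g, w_t,
                     v_t, tau_rise, tau_decay, w_s, v_s, T_s, P,
                     phase_locked, osc_emission, env, n_phi, bias, tau,
                     extra_stimulus,
                     record_surfaces, sensors_ring, sensors_axial,
                     correction_step, correction_max_iter, contact_tol) {
  if (dim != 2 && dim != 3) stop("'dim' must be 2 or 3")
  dir <- if (is.character(orientation)) {
    switch(match.arg(orientation, c("vertical", "horizontal")),
           vertical = c(0, 0, -1), horizontal = c(1, 0, 0))
  } else orientation / sqrt(sum(orientation^2))
  if (is.null(origin)) origin <- -zone_length * dir
  root <- root_state(direction = dir, origin = origin,
                     zone_length = zone_length, dt = dt, G_base = G_base,
                     D = D)
  n <- root$n
  d_grid <- zone_length - (seq_len(n) - 1L) * root$seg_len  # segment d's
  phi_grid <- if (dim == 2) c(0, pi) else
    seq(-pi, pi, length.out = n_phi)
  G_b <- baseline_surface(d_grid, peak_d = peak_d,
                          zone_length = zone_length, G_base = G_base)
  if (is.null(T_s)) T_s <- 2 * pi / P
  stims <- list()
  if (w_g != 0) stims$gravity <- stimulus_field("gravity", v_g, w_g)
  if (w_t != 0) stims$touch <- stimulus_field("touch", v_t, w_t)
  if (w_s != 0) stims$resource <- stimulus_field("resource", v_s, w_s)
  if (!is.null(extra_stimulus))
    stims$scripted <- stimulus_field("scripted", extra_stimulus$v,
                                     extra_stimulus$w)
  n_steps <- round(duration / dt)
  nphi <- length(phi_grid)
  iphi0 <- which.min(abs(phi_grid))          # column of phi = 0
  # opposite-flank column index (grid endpoints alias the same angle)
  iopp_map <- if (dim == 2) c(2L, 1L) else {
    half <- (nphi - 1L) %/% 2L
    ((seq_len(nphi) - 1L + half) %% (nphi - 1L)) + 1L
  }
  jpeak <- which.min(abs(d_grid - peak_d))
  list(
    root = root, t = 0, k = 0L, n_steps = n_steps, dt = dt, dim = dim,
    D = D, d_grid = d_grid, phi_grid = phi_grid, nphi = nphi,
    iphi0 = iphi0, iopp_map = iopp_map, jpeak = jpeak,
    G_b = G_b, G_base = G_base, peak_d = peak_d,
    zone_length = zone_length, d_cap = d_cap, p_cap = p_cap,
    S_a = matrix(bias, n, nphi), bias = bias, tau = tau,
    stims = stims, w_g = w_g, w_t = w_t, w_s = w_s,
    osc = oscillator_state(T_s = max(T_s, .Machine$double.xmin),
                           phase_locked = phase_locked),
    T_s = T_s, osc_emission = osc_emission,
    tau_rise = tau_rise, tau_decay = tau_decay,
    extra_stimulus = extra_stimulus,
    env = env, has_obstacles = length(env$obstacles) > 0L,
    has_field = !is.null(env$field),
    phi_g_prev = 0, phi_t_prev = 0, touch_state = 0, last_contact = NULL,
    C_prev = NA_real_, G_prev = G_base,
    sensors_ring = sensors_ring, sensors_axial = sensors_axial,
    correction_step = correction_step,
    correction_max_iter = correction_max_iter,
    contact_tol = contact_tol,
    record_surfaces = record_surfaces,
    surfaces = if (record_surfaces) vector("list", n_steps),
    rec = matrix(NA_real_, n_steps, 16L),
    trapped_steps = 0L,
    params = list(duration = duration, dt = dt, dim = dim,
                  orientation = dir, peak_d = peak_d,
                  zone_length = zone_length, G_base = G_base, D = D,
                  w_g = w_g, v_g = v_g, w_t = w_t, v_t = v_t,
                  tau_rise = tau_rise, tau_decay = tau_decay,
                  w_s = w_s, v_s = v_s, T_s = T_s,
                  phase_locked = phase_locked, osc_emission = osc_emission,
                  n_phi = n_phi,
                  bias = bias, tau = tau))
}

# One full simulation step at time st$t -> st$t + dt.  `extra_obstacles`
# (e.g. the other roots of a multi-root scenario) are added to the
# environment's obstacle set for this step only.
sim_step <- function(st, extra_obstacles = NULL) {
  dt <- st$dt
  t <- st$t
  root <- st$root
  tipA <- tip_frame(root)
  tipc <- tip_position(root)
  obstacles <- st$env$obstacles
  if (!is.null(extra_obstacles)) obstacles <- c(obstacles, extra_obstacles)
  all_obstacles <- obstacles
  have_obs <- length(obstacles) > 0L
  s_g <- s_t <- s_s <- 0
  C_now <- NA_real_

  # -- stimulus emissions at the tip --
  if (!is.null(st$stims$gravity)) {
    alpha_g <- gravity_angle(tipA[, 3L], st$env$gravity)
    st$phi_g_prev <- top_side_angle(tipA, st$env$gravity, st$phi_g_prev)
    s_g <- gravity_strength(alpha_g)
    st$stims$gravity <- emit_stimulus(st$stims$gravity, t, s_g,
                                      st$phi_g_prev)
  }
  # the touch event seen by the signaling pathway is the intersected
  # sensory-point set found right after the previous growth step
  contact <- st$last_contact
  if (!is.null(st$stims$touch)) {
    st$touch_state <- touch_signal_step(st$touch_state, contact, dt,
                                        st$tau_rise, st$tau_decay)
    if (!is.null(contact)) st$phi_t_prev <- contact$phi_t
    s_t <- st$touch_state
    # the inhibitory strength acts on the flank opposite the contact;
    # by antisymmetry the touched flank is excited, so the apex bends
    # away from the obstacle while sliding along it
    st$stims$touch <- emit_stimulus(st$stims$touch, t, s_t,
                                    st$phi_t_prev + pi)
  }
  if (!is.null(st$stims$resource) && st$has_field) {
    C_now <- concentration(st$env$field, tipc)
    if (st$k > 0L) {
      dC <- perceived_gradient(C_now, st$C_prev, dt, st$G_prev)
      st$osc <- oscillator_step(st$osc, dC, dt, st$dim)
      s_s <- st$osc$s_s
    } else s_s <- 0
    phi_s <- if (st$osc_emission == "alternating") 0 else
      if (is.null(st$osc$phi)) st$osc$phi0 else st$osc$phi
    st$C_prev <- C_now
    st$stims$resource <- emit_stimulus(st$stims$resource, t, s_s, phi_s)
  } else if (st$has_field) {
    C_now <- concentration(st$env$field, tipc)
  }
  if (!is.null(st$stims$scripted)) {
    em <- st$extra_stimulus$fun(t)
    st$stims$scripted <- emit_stimulus(st$stims$scripted, t, em$s, em$phi)
  }

  # -- signal surfaces and aggregation --
  S_list <- lapply(st$stims, propagate, t = t, d = st$d_grid,
                   phi = st$phi_grid, D = st$D)
  w <- vapply(st$stims, `[[`, numeric(1), "w")
  st$S_a <- aggregate_step(st$S_a, S_list, w, st$bias, st$tau, dt)
  G_s <- st$G_b * st$S_a

  # -- differential growth extraction and kinematic step --
  imax <- max.col(G_s, ties.method = "first")
  n <- root$n
  Gl <- G_s[cbind(seq_len(n), imax)]
  Gr <- G_s[cbind(seq_len(n), st$iopp_map[imax])]
  phimax <- st$phi_grid[imax]
  root <- step_root(root, Gl, Gr, phimax, dt)
  ext <- attr(root, "extension")

  trapped <- FALSE
  if (have_obs) {
    # sensory points all lie within d_cap + r of the tip, so obstacles
    # farther than that from the tip center cannot be touched this step
    tipc1 <- root$centers[nrow(root$centers), ]
    reach <- st$d_cap + 0.5 * st$D + 0.5
    obstacles <- obstacles[vapply(obstacles, function(ob)
      signed_clearance(ob, tipc1) < reach, logical(1))]
  }
  if (length(obstacles)) {
    st$last_contact <- detect_contact(root, obstacles, p_cap = st$p_cap,
                                      tol = st$contact_tol)
    if (!is.null(st$last_contact) && st$last_contact$depth > 0) {
      root <- passive_correction(root, obstacles, st$correction_step,
                                 st$correction_max_iter, st$p_cap)
      trapped <- attr(root, "trapped")
    }
  } else if (have_obs) {
    st$last_contact <- NULL
  }
  st$root <- root
  st$G_prev <- max(ext / dt, 1e-9)
  st$k <- st$k + 1L
  st$t <- t + dt

  # -- per-step record --
  tipc2 <- tip_position(root)
  alpha_deg <- gravity_angle(tip_frame(root)[, 3L], st$env$gravity) * 180 / pi
  obs_angle <- NA_real_
  if (have_obs && all_obstacles[[1L]]$kind == "plane")
    obs_angle <- tip_obstacle_angle(root, all_obstacles[[1L]])
  ev <- st$last_contact
  st$rec[st$k, ] <- c(st$t, tipc2, alpha_deg,
                      if (st$has_field) concentration(st$env$field, tipc2)
                        else NA_real_,
                      G_s[st$jpeak, st$iphi0] / st$G_b[st$jpeak],
                      max(Gl - Gr), as.numeric(!is.null(ev)),
                      obs_angle, s_g, s_t, s_s,
                      if (is.null(ev)) NA_real_ else ev$d_t,
                      if (is.null(ev)) NA_real_ else ev$phi_t,
                      if (is.null(ev)) NA_real_ else ev$alpha_t)
  if (st$record_surfaces)
    st$surfaces[[st$k]] <- list(t = st$t, S_a = st$S_a, G_s = G_s)
  if (trapped) st$trapped_steps <- st$trapped_steps + 1L
  st
}

sim_finalize <- function(st) {
  trace <- as.data.frame(st$rec[seq_len(st$k), , drop = FALSE])
  names(trace) <- c("t", "x", "y", "z", "tip_angle", "C", "g_side",
                    "diff_amp", "contact", "obstacle_angle",
                    "s_g", "s_t", "s_s", "d_t", "phi_t", "alpha_t")
  structure(list(root = st$root, trace = trace, params = st$params,
                 env = st$env, trapped_steps = st$trapped_steps,
                 surfaces = if (st$record_surfaces) st$surfaces),
            class = "root_sim")
}

#' Nutation metrics of a simulated root
#'
#' Applies the growth-rate-extrema quantification to a finished run: the
#' one-side normalized growth-rate series is scanned for turning points,
#' each mapped to the tip position at that instant, and periods (time
#' between same-type extrema), per-cycle amplitudes, and the number of
#' complete cycles are derived.
#'
#' @param sim A `root_sim`.
#' @param prominence Extremum prominence threshold (see
#'   [nutation_extrema()]).
#' @return A `nutation_metrics` list (see [nutation_period_amplitude()]).
#' @export
nutation_metrics <- function(sim, prominence = 0.01) {
  tr <- sim$trace
  ex <- nutation_extrema(tr$g_side, tr$t, prominence)
  pos <- as.matrix(tr[ex$index, c("x", "y", "z")])
  nutation_period_amplitude(ex, pos)
}
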