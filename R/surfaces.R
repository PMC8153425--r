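# Signal network: baseline growth surface (root zonation), per-stimulus
# signal surfaces with finite-speed axial propagation, and the leaky
# aggregation that yields the stimuli growth response surface
# G_s = G_b * S_a.
#
# The aggregation step is the forward-Euler discretization of a
# continuous-time recurrent network: each surface element (d, phi) is a
# leaky node with time constant tau relaxing toward the weighted sum of
# incoming stimulus signals plus a bias.

#' Baseline growth surface (root zonation)
#'
#' A Gaussian elongation-rate profile over arc distance from the tip with
#' standard deviation `0.1 * zone_length`, peaked at `peak_d`, and constant
#' over the circumferential angle.  The profile is normalized so that the
#' summed elongation rate over the zone equals `G_base` (i.e. the root
#' extends by `G_base * dt` per step under baseline conditions).
#'
#' @param d Arc distances from the tip at which to evaluate (units of D);
#'   typically the per-segment grid `seq(zone_length, seg_len, by = -seg_len)`.
#' @param peak_d Zonation peak distance from the tip (units of D); 1.5 and
#'   3.0 are the two regimes studied in the experiments.
#' @param zone_length Elongation-zone length (units of D, default 6).
#' @param G_base Average (zone-total) growth rate, D/hour (default 1).
#' @return Baseline rates at `d` (D/hour), summing to `G_base`.
#' @export
baseline_surface <- function(d, peak_d = 3, zone_length = 6, G_base = 1) {
  if (peak_d <= 0 || peak_d >= zone_length)
    stop("'peak_d' must lie inside the elongation zone")
  g <- exp(-0.5 * ((d - peak_d) / (0.1 * zone_length))^2)
  g * (G_base / sum(g))
}

#' Create a stimulus signal field
#'
#' A stimulus is a time series of signal emissions (strength in `[-1, 1]`
#' and a circumferential peak angle), generated at the tip (`d = 0`) and
#' propagated axially toward the base at finite speed with no attenuation.
#'
#' @param id Stimulus name (`"gravity"`, `"touch"`, `"resource"`, ...).
#' @param velocity Axial propagation speed `v_i` (D/hour, `> 0`; a zero
#'   velocity is accepted and yields an everywhere-zero surface).
#' @param weight Sensitivity `w_i` multiplying this stimulus in the
#'   aggregation (dimensionless; constant over time and space).
#' @param n_reserve Number of emission slots to preallocate.
#' @return An object of class `stimulus_field` with an empty emission
#'   history.
#' @export
stimulus_field <- function(id, velocity, weight, n_reserve = 64L) {
  if (velocity < 0) stop("propagation velocity must be non-negative")
  structure(list(id = id, v = velocity, w = weight,
                 times = numeric(n_reserve), strength = numeric(n_reserve),
                 cphi = numeric(n_reserve), sphi = numeric(n_reserve),
                 k = 0L),
            class = "stimulus_field")
}

#' Record a stimulus emission
#'
#' Appends one emission sample `(t, strength, phi_peak)` to the source
#' history.  Emission times must be non-decreasing.
#'
#' @param stim A [stimulus_field()].
#' @param t Emission time (hours).
#' @param strength Signal strength in `[-1, 1]` (negative = inhibition).
#' @param phi_peak Circumferential angle of the excitation peak (radians).
#' @return The updated `stimulus_field`.
#' @export
emit_stimulus <- function(stim, t, strength, phi_peak) {
  if (strength < -1 || strength > 1)
    stop("stimulus strength must lie in [-1, 1]")
  k <- stim$k + 1L
  if (k > length(stim$times)) {           # grow storage geometrically
    grow <- function(x) c(x, numeric(length(x)))
    stim$times <- grow(stim$times); stim$strength <- grow(stim$strength)
    stim$cphi <- grow(stim$cphi); stim$sphi <- grow(stim$sphi)
  }
  stim$times[k] <- t
  stim$strength[k] <- strength
  stim$cphi[k] <- cos(phi_peak)
  stim$sphi[k] <- sin(phi_peak)
  stim$k <- k
  stim
}

# Delayed source lookup: strength and peak angle that apply at arc
# distance d (vector) at time t.  The signal emitted at time te arrives at
# distance d at te + d * D / v; values are linearly interpolated between
# emission samples (the angle via its unit vector), zero before the first
# emission arrives.
stimulus_at <- function(stim, t, d, D = 1) {
  nd <- length(d)
  if (stim$k == 0L || stim$v <= 0)
    return(list(s = numeric(nd), phi = numeric(nd)))
  te <- t - d * D / stim$v
  tt <- stim$times[seq_len(stim$k)]
  s <- numeric(nd)
  phi <- numeric(nd)
  ok <- te >= tt[1L]
  if (any(ok)) {
    teo <- pmin(te[ok], tt[stim$k])
    i <- findInterval(teo, tt)
    i2 <- pmin(i + 1L, stim$k)
    dtg <- tt[i2] - tt[i]
    f <- ifelse(dtg > 0, (teo - tt[i]) / dtg, 0)
    s[ok] <- (1 - f) * stim$strength[i] + f * stim$strength[i2]
    cph <- (1 - f) * stim$cphi[i] + f * stim$cphi[i2]
    sph <- (1 - f) * stim$sphi[i] + f * stim$sphi[i2]
    phi[ok] <- atan2(sph, cph)
  }
  list(s = s, phi = phi)
}

# Antisymmetric-linear circumferential profile: 1 at the peak angle, 0 at
# +/- pi/2 from it, -1 at the opposite flank; linear in angular distance.
phi_profile <- function(dphi) {
  a <- dphi - 2 * pi * round(dphi / (2 * pi))   # wrap to [-pi, pi]
  1 - 2 * abs(a) / pi
}

#' Propagated stimulus value
#'
#' Value of the stimulus signal response surface `S_i(t, d, phi)`: the
#' source strength emitted at `t - d * D / v_i` (pure advection, no
#' attenuation; zero before the signal first reaches `d`), modulated over
#' the circumference by the antisymmetric-linear profile around the peak
#' angle recorded at emission time.
#'
#' @param stim A [stimulus_field()] with a recorded emission history.
#' @param t Evaluation time (hours).
#' @param d Arc distance(s) from the tip (units of D).
#' @param phi Circumferential angle(s), radians.  If `d` and `phi` are both
#'   vectors a `length(d) x length(phi)` matrix is returned.
#' @param D Root diameter.
#' @return Signal values in `[-1, 1]`.
#' @export
propagate <- function(stim, t, d, phi, D = 1) {
  src <- stimulus_at(stim, t, d, D)
  if (length(phi) > 1L || length(d) > 1L) {
    dphi <- outer(-src$phi, phi, `+`)
    src$s * phi_profile(dphi)
  } else {
    src$s * phi_profile(phi - src$phi)
  }
}

#' Leaky aggregation of stimulus surfaces
#'
#' One forward-Euler step of the leaky integrator
#' `S_a <- (1 - dt/tau) * S_a + (dt/tau) * f_a(sum_i w_i S_i + b)` with
#' linear activation `f_a(x) = x`.  With `tau = dt` the update is
#' instantaneous.  The result is floored at 0: strong net inhibition stalls
#' growth rather than shrinking the root.
#'
#' @param S_a_prev Aggregated surface from the previous step (any numeric
#'   shape).
#' @param S_list List of stimulus surfaces `S_i` (same shape).
#' @param w Stimulus weights (one per surface).
#' @param b Bias (default 1, so that `S_a = 1` and `G_s = G_b` without
#'   stimuli).
#' @param tau Decay time constant(s), hours; must satisfy `tau >= dt`.
#' @param dt Time step (hours).
#' @return The updated aggregated surface, clamped to `>= 0`.
#' @export
aggregate_step <- function(S_a_prev, S_list, w, b = 1, tau, dt) {
  if (any(tau < dt)) stop("'tau' must be >= dt for a stable update")
  drive <- b
  if (length(S_list)) {
    stopifnot(length(w) == length(S_list))
    for (i in seq_along(S_list)) drive <- drive + w[i] * S_list[[i]]
  }
  S_a <- S_a_prev + (dt / tau) * (drive - S_a_prev)
  pmax(S_a, 0)
}
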