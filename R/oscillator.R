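# Internal oscillatory apparatus for resource exploration: a sinusoidal
# tip signal whose phase velocity is modulated by the resource-concentration
# gradient perceived at the tip (the basis of gradient klinotaxis).

#' Perceived resource gradient at the tip
#'
#' Concentration change between consecutive steps normalized by the
#' distance grown during the step:
#' `delta_C = (C_now - C_prev) / (dt * G_avr)`.
#'
#' @param C_now,C_prev Concentration at the tip at the current and previous
#'   step.
#' @param dt Time step (hours).
#' @param G_avr Average growth rate over the step (D/hour, `> 0`).
#' @return The normalized gradient (dimensionless; concentration change per
#'   diameter grown).
#' @export
perceived_gradient <- function(C_now, C_prev, dt, G_avr) {
  if (any(G_avr <= 0)) stop("'G_avr' must be positive")
  (C_now - C_prev) / (dt * G_avr)
}

#' Create the oscillator state
#'
#' @param P Baseline period in hours (used if `T_s` missing).
#' @param T_s Baseline angular frequency (rad/hour), `2 * pi / P`.
#' @param phi0 Emission-angle offset at zero phase (default `pi`).
#' @param phase_locked If `FALSE` (default) the emission angle advances
#'   with wall-clock time as `phi = phi0 + T_s * t`, so the gradient only
#'   modulates the strength phase `t_s` and the two slowly beat against
#'   each other; if `TRUE` the angle advances with the modulated phase
#'   `t_s`, locking spatial and temporal phase (a much tighter feedback
#'   loop that produces faster, more persistent climbing).
#' @return An object of class `oscillator_state`.
#' @export
oscillator_state <- function(P = 10, T_s = 2 * pi / P, phi0 = pi,
                             phase_locked = TRUE) {
  if (T_s <= 0) stop("'T_s' must be positive")
  structure(list(T_s = T_s, t_s = 0, t = 0, phi0 = phi0,
                 phase_locked = phase_locked),
            class = "oscillator_state")
}

#' Advance the internal oscillator by one step
#'
#' Updates the internal phase
#' `t_s <- t_s + dt * T_s * (1 + sign(delta_C) / (1 + exp(|delta_C|)))`:
#' the oscillation accelerates (up to 1.5x near `delta_C = 0+`) while the
#' perceived concentration rises and decelerates (down to 0.5x) while it
#' falls, the modulation factor returning to 1 for large `|delta_C|` --
#' sensitive primarily to the sign of the change.  `sign(0) = 0` so a
#' uniform field leaves the period exactly at `P`.
#'
#' @param osc An [oscillator_state()].
#' @param delta_C Perceived gradient from [perceived_gradient()].
#' @param dt Time step (hours).
#' @param dim 2 or 3: in 3-D the emission angle sweeps the circumference;
#'   in 2-D it is fixed at 0 (the signal's antisymmetric profile supplies
#'   the opposite flank).
#' @return The updated state; fields `s_s` (emitted strength `sin(t_s)`)
#'   and `phi` (emission angle) hold the current output.
#' @export
oscillator_step <- function(osc, delta_C, dt, dim = 3) {
  rate <- 1 + sign(delta_C) / (1 + exp(abs(delta_C)))
  osc$t_s <- osc$t_s + dt * osc$T_s * rate
  osc$t <- osc$t + dt
  osc$s_s <- sin(osc$t_s)
  ph <- osc$phi0 + if (osc$phase_locked) osc$t_s else osc$T_s * osc$t
  osc$phi <- ph - 2 * pi * round(ph / (2 * pi))
  osc
}
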