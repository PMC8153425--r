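# Gravitropic stimulus: generated at the root cap from the angle between
# the tip direction and gravity, emitted along the top side of the root.

#' Gravitropic signal strength
#'
#' Maps the deviation angle `alpha_g` between the tip direction and the
#' gravity vector to the emitted signal strength: `2 * alpha_g / pi` for
#' `alpha_g <= pi/2` and saturated at 1 beyond (a tip pointing upward
#' signals no more strongly than one perpendicular to gravity).
#'
#' @param alpha_g Deviation angle in radians, in `[0, pi]` (vectorized).
#' @return Signal strength in `[0, 1]`.
#' @export
gravity_strength <- function(alpha_g) {
  if (any(alpha_g < -1e-12 | alpha_g > pi + 1e-12))
    stop("'alpha_g' must lie in [0, pi]")
  pmin(1, 2 * pmax(alpha_g, 0) / pi)
}

#' Top-side circumferential angle of the root tip
#'
#' The angle `phi_g`, measured from the tip frame's reference (y) axis in
#' the tip cross-sectional plane, of the projection of the "up" direction
#' `-g`.  The maximal gravitropic excitation propagates along this angle.
#' When the tip is (anti)parallel to gravity the projection vanishes and
#' the previous angle is kept -- the emitted strength is 0 (or the
#' direction is irrelevant) so the choice is inert.
#'
#' @param tip_frame 3x3 orthonormal tip frame (columns x, y, z).
#' @param g Gravity direction (non-zero 3-vector).
#' @param prev Fallback angle when the projection is degenerate.
#' @return `phi_g` in radians.
#' @export
top_side_angle <- function(tip_frame, g, prev = 0) {
  gn <- sqrt(sum(g^2))
  if (gn < 1e-300) stop("zero gravity vector")
  up <- -g / gn
  px <- sum(tip_frame[, 1L] * up)
  py <- sum(tip_frame[, 2L] * up)
  if (px * px + py * py < 1e-24) return(prev)
  atan2(px, py)     # phi measured from y toward x: u(phi) = sin(phi) x + cos(phi) y
}

#' Tip-to-gravity deviation angle
#'
#' @param tip_dir Tip tangent (3-vector, base to tip).
#' @param g Gravity direction.
#' @return `alpha_g` in `[0, pi]`, radians.
#' @export
gravity_angle <- function(tip_dir, g) {
  ct <- sum(tip_dir * g) / sqrt(sum(tip_dir^2) * sum(g^2))
  acos(pmin(1, pmax(-1, ct)))
}
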