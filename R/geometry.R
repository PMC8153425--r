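# Root apex geometry: cross-section chain, differential-growth kinematics,
# and fixed-length elongation-zone resampling.
#
# The apex is represented by n + 1 cross-section "joints" ordered base -> tip.
# Joint i carries a center (3-vector, units of the diameter D) and an
# orthonormal frame A (columns x, y, z; z points tip-ward along the local
# axis, y is the reference-curve direction from which circumferential angles
# phi are measured).  Consecutive joints delimit the n growing segments.

#' Root-cap radius profile
#'
#' Radius of the root cross-section as a function of arc distance from the
#' tip.  Within the cap region (`d < d_cap`) the radius tapers as a power law
#' `0.5 * D * (d / d_cap)^p_cap`; beyond it the root is a cylinder of radius
#' `0.5 * D`.
#'
#' @param d Arc distance from the tip, in units of `D` (vectorized, `>= 0`).
#' @param d_cap Cap length threshold in units of `D` (default 1.5).
#' @param p_cap Cap curvature exponent in (0, 1) (default 0.4).
#' @param D Root diameter (default 1; all lengths are multiples of `D`).
#' @return Radii in units of `D`, continuous at `d = d_cap`.
#' @export
#' @examples
#' cap_radius(c(0, 0.75, 2))
cap_radius <- function(d, d_cap = 1.5, p_cap = 0.4, D = 1) {
  if (any(d < 0)) stop("'d' must be non-negative")
  if (d_cap <= 0) stop("'d_cap' must be positive")
  if (p_cap <= 0 || p_cap >= 1) stop("'p_cap' must be in (0, 1)")
  r <- rep(0.5 * D, length(d))
  inside <- d < d_cap
  r[inside] <- 0.5 * D * (d[inside] / d_cap)^p_cap
  r
}

#' Bend geometry from opposite-flank elongation rates
#'
#' Converts the elongation rates at the fastest-growing flank (`G_left`, at
#' circumferential angle `phi`) and the opposite flank (`G_right`, at
#' `phi + pi`) into the bend angle `theta = |G_left - G_right| * dt / D` and
#' the curvature radius `R_c = (D / 2) * (G_left + G_right) /
#' (G_left - G_right)`.  Equal rates give straight extension (`theta = 0`,
#' infinite `R_c`).
#'
#' @param G_left,G_right Elongation rates (D/hour), `G_left >= G_right >= 0`.
#' @param dt Time step in hours.
#' @param D Root diameter.
#' @param phi Circumferential angle of maximal growth w.r.t. the reference
#'   curve, radians in `[-pi, pi]`.
#' @return A list of class `bend_step` with `theta`, `R_c` (`Inf` when
#'   straight), `phi`, `G_left`, `G_right`, `G_avr`, `dt`.
#' @export
bend_from_rates <- function(G_left, G_right, dt, D = 1, phi = 0) {
  if (G_right < 0 || G_left < G_right)
    stop("need G_left >= G_right >= 0")
  theta <- (G_left - G_right) * dt / D
  R_c <- if (theta > 0) 0.5 * D * (G_left + G_right) / (G_left - G_right) else Inf
  structure(
    list(theta = theta, R_c = R_c, phi = phi,
         G_left = G_left, G_right = G_right,
         G_avr = 0.5 * (G_left + G_right), dt = dt),
    class = "bend_step")
}

# Rodrigues rotation about a unit axis (3-vector) by angle (radians).
rot3 <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle); v <- 1 - c_
  x <- axis[1L]; y <- axis[2L]; z <- axis[3L]
  matrix(c(c_ + x * x * v, x * y * v + z * s_, x * z * v - y * s_,
           x * y * v - z * s_, c_ + y * y * v, y * z * v + x * s_,
           x * z * v + y * s_, y * z * v - x * s_, c_ + z * z * v),
         3L, 3L)
}

# Local bend transform of one segment: chord displacement `v` (local frame,
# includes the axial extension) and no-twist rotation `M`.  The direction of
# maximal growth in the local frame is u(phi) = (sin phi, cos phi, 0); the
# arc of length G_avr * dt curves AWAY from the fast flank, i.e. toward
# -u(phi), while z tips by theta in the same plane.
bend_transform <- function(bend) {
  ext <- bend$G_avr * bend$dt
  if (bend$theta <= 0) {
    return(list(v = c(0, 0, ext), M = diag(3)))
  }
  th <- bend$theta; Rc <- bend$R_c
  sp <- sin(bend$phi); cp <- cos(bend$phi)
  lat <- Rc * (1 - cos(th))
  v <- c(-sp * lat, -cp * lat, Rc * sin(th))
  M <- rot3(c(cp, -sp, 0), th)
  list(v = v, M = M)
}

#' Advance a single cross-section by one bend step
#'
#' Applies the extension-plus-bend kinematics to one cross-section: the
#' center is displaced by the chord of the newly grown arc expressed in the
#' section's own frame, and the frame is post-multiplied by the no-twist
#' bend rotation.
#'
#' @param section A list with `center` (3-vector) and `frame` (3x3
#'   orthonormal, columns x, y, z, `det = +1`).
#' @param bend A `bend_step` from [bend_from_rates()].
#' @return The updated section (same structure).
#' @export
advance_section <- function(section, bend) {
  A <- section$frame
  if (!is_orthonormal(A))
    stop("section frame is not orthonormal")
  bt <- bend_transform(bend)
  list(center = as.vector(section$center + A %*% bt$v),
       frame = A %*% bt$M)
}

# Orthonormality check with det +1.
is_orthonormal <- function(A, tol = 1e-9) {
  max(abs(crossprod(A) - diag(3))) < tol && abs(det(A) - 1) < tol
}

# Gram-Schmidt re-orthonormalization anchored on the local axis (z), then
# the reference direction (y).  Applied every time a frame is stored so
# floating-point error cannot compound along the chain or across steps.
ortho3 <- function(A) {
  z <- A[, 3L]; z <- z / sqrt(sum(z * z))
  y <- A[, 2L]; y <- y - sum(y * z) * z; y <- y / sqrt(sum(y * y))
  x <- c(y[2L] * z[3L] - y[3L] * z[2L],
         y[3L] * z[1L] - y[1L] * z[3L],
         y[1L] * z[2L] - y[2L] * z[1L])
  cbind(x, y, z, deparse.level = 0)
}

#' Construct the initial root state
#'
#' The initial root is straight, spans one elongation-zone length, and is
#' discretized into `n = zone_length / (dt * G_base)` segments of equal
#' length (60 segments of 0.1 D with the defaults).
#'
#' @param direction Unit 3-vector of the growth direction (base to tip);
#'   default vertical, i.e. `c(0, 0, -1)` with gravity along -z.
#' @param reference Unit 3-vector for the phi = 0 (reference-curve)
#'   direction; must be orthogonal to `direction`.  Default picks a
#'   convenient perpendicular.
#' @param origin Base position (3-vector).
#' @param zone_length Elongation-zone length in units of `D` (default 6).
#' @param dt Time step (hours, default 0.1).
#' @param G_base Baseline average growth rate (D/hour, default 1).
#' @param D Root diameter (default 1).
#' @return An object of class `root_state`: list with `centers`
#'   ((n+1) x 3, base -> tip), `frames` (3 x 3 x (n+1)), `n` segments,
#'   `seg_len`, `zone_length`, `D`, `t`, and the append-only `mature`
#'   trace (centers and frames of cross-sections frozen out of the zone).
#' @export
root_state <- function(direction = c(0, 0, -1), reference = NULL,
                       origin = c(0, 0, 0), zone_length = 6,
                       dt = 0.1, G_base = 1, D = 1) {
  z <- direction / sqrt(sum(direction^2))
  if (is.null(reference)) {
    ref <- if (abs(z[3L]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    y <- ref - sum(ref * z) * z
  } else {
    y <- reference - sum(reference * z) * z
    if (sqrt(sum(y^2)) < 1e-12)
      stop("'reference' must not be parallel to 'direction'")
  }
  y <- y / sqrt(sum(y^2))
  x <- c(y[2L] * z[3L] - y[3L] * z[2L],
         y[3L] * z[1L] - y[1L] * z[3L],
         y[1L] * z[2L] - y[2L] * z[1L])
  A <- cbind(x, y, z, deparse.level = 0)
  n <- as.integer(round(zone_length / (dt * G_base)))
  seg_len <- zone_length / n
  s <- seq(0, zone_length, by = seg_len)
  centers <- cbind(origin[1L] + s * z[1L],
                   origin[2L] + s * z[2L],
                   origin[3L] + s * z[3L])
  frames <- array(A, dim = c(3L, 3L, n + 1L))
  structure(
    list(centers = centers, frames = frames, n = n, seg_len = seg_len,
         zone_length = zone_length, D = D, t = 0,
         mature = list(centers = matrix(numeric(0), 0L, 3L),
                       frames = array(numeric(0), dim = c(3L, 3L, 0L)))),
    class = "root_state")
}

#' Tip position and tangent of a root state
#' @param root A `root_state`.
#' @return `tip_position()`: 3-vector; `tip_frame()`: 3x3 matrix whose third
#'   column is the tip tangent (pointing tip-ward).
#' @export
tip_position <- function(root) root$centers[nrow(root$centers), ]

#' @rdname tip_position
#' @export
tip_frame <- function(root) root$frames[, , dim(root$frames)[3L]]

# Arc distances from the tip of each joint (base -> tip order).
joint_distances <- function(root) {
  n1 <- nrow(root$centers)
  root$seg_len * ((n1 - 1L):0L)
}

#' Grow all segments for one time step
#'
#' Sweeps the chain base -> tip.  Segment `j` (between joints `j` and
#' `j + 1`, evaluated at arc distance `d_j` from the tip) extends by
#' `G_avr(d_j) * dt` and bends by `theta_j` toward the slow flank; the
#' resulting rigid roto-translation is propagated to every tip-ward joint.
#' Rates are given per segment at the angle of maximal growth.
#'
#' @param root A `root_state`.
#' @param G_left,G_right Numeric vectors (length `n`, base -> tip): the
#'   maximal elongation rate over phi and the rate at the opposite flank.
#' @param phi Angle of maximal growth per segment (radians).
#' @param dt Time step (hours).
#' @return The updated (elongated, not yet resampled) `root_state`; the
#'   attribute `"extension"` holds the total polyline elongation.
#' @export
grow_step <- function(root, G_left, G_right, phi, dt) {
  n <- root$n
  stopifnot(length(G_left) == n, length(G_right) == n, length(phi) == n)
  if (any(G_left < G_right)) stop("G_left must dominate G_right")
  D <- root$D
  c0 <- root$centers
  f0 <- root$frames
  len0 <- sum(sqrt(rowSums((c0[-1L, , drop = FALSE] -
                              c0[-(n + 1L), , drop = FALSE])^2)))
  # Relative-transform sweep (base -> tip).  The world-frame statement of
  # the kinematics ("bend segment j, rigidly carry everything tip-ward")
  # is algebraically equivalent to updating the pose of joint j+1 relative
  # to joint j:
  #   A'_{j+1} = A'_j * M_j * (A_j^T A_{j+1}),
  #   c'_{j+1} = c'_j + A'_j * (v_j + M_j * A_j^T (c_{j+1} - c_j)),
  # with primes the updated poses and unprimed the pre-step ones.  This
  # forward recomposition uses only products of rotations and is
  # numerically stable, unlike accumulating world-frame conjugations.
  centers <- c0
  frames <- f0
  for (j in seq_len(n)) {
    Ao <- f0[, , j]
    w <- as.vector(crossprod(Ao, c0[j + 1L, ] - c0[j, ]))  # old local offset
    Rrel <- crossprod(Ao, f0[, , j + 1L])
    gl <- G_left[j]; gr <- G_right[j]
    dG <- gl - gr
    if (dG <= 0) {
      vloc <- c(0, 0, 0.5 * (gl + gr) * dt)
      off <- vloc + w
      Rnew <- Rrel
    } else {
      theta <- dG * dt / D
      Rc <- 0.5 * D * (gl + gr) / dG
      sp <- sin(phi[j]); cp <- cos(phi[j])
      lat <- Rc * (1 - cos(theta))
      M <- rot3(c(cp, -sp, 0), theta)
      off <- c(-sp * lat, -cp * lat, Rc * sin(theta)) + as.vector(M %*% w)
      Rnew <- M %*% Rrel
    }
    Aj <- frames[, , j]
    centers[j + 1L, ] <- centers[j, ] + as.vector(Aj %*% off)
    frames[, , j + 1L] <- ortho3(Aj %*% Rnew)
  }
  root$centers <- centers
  root$frames <- frames
  len1 <- sum(sqrt(rowSums((centers[-1L, , drop = FALSE] -
                              centers[-(n + 1L), , drop = FALSE])^2)))
  attr(root, "extension") <- len1 - len0
  root
}

# Axis-angle of the relative rotations between consecutive frames.
# Returns list(angle = vector, axis = m x 3), stable for small angles.
relative_rotations <- function(frames) {
  m <- dim(frames)[3L] - 1L
  ang <- numeric(m)
  axis <- matrix(0, m, 3L)
  axis[, 3L] <- 1
  for (k in seq_len(m)) {
    Rr <- crossprod(frames[, , k], frames[, , k + 1L])
    w <- c(Rr[3L, 2L] - Rr[2L, 3L],
           Rr[1L, 3L] - Rr[3L, 1L],
           Rr[2L, 1L] - Rr[1L, 2L])
    s2 <- 0.5 * sqrt(sum(w^2))             # sin(angle)
    c2 <- 0.5 * (Rr[1L, 1L] + Rr[2L, 2L] + Rr[3L, 3L] - 1)  # cos(angle)
    a <- atan2(s2, c2)
    if (s2 > 1e-14) {
      ang[k] <- a
      axis[k, ] <- w / (2 * s2)
    }
  }
  list(angle = ang, axis = axis)
}

#' Resample the elongation zone to fixed-length sections
#'
#' Re-splits the apical `zone_length` of the (elongated) centerline into `n`
#' equal sections by arc length, measured from the tip.  Centers are
#' interpolated linearly on the polyline; frames are interpolated by
#' spherical-linear interpolation of the relative rotation between the
#' bracketing joints, which preserves orthonormality and the as-grown 3-D
#' orientation.  Material that leaves the zone at the base is appended to
#' the frozen `mature` trace and never moves again.
#'
#' @param root An elongated `root_state` (output of [grow_step()]).
#' @return The resampled `root_state` with `n + 1` joints spaced
#'   `seg_len` apart along the polyline.
#' @export
resample_root <- function(root) {
  centers <- root$centers
  frames <- root$frames
  n <- root$n
  seg <- centers[-1L, , drop = FALSE] - centers[-nrow(centers), , drop = FALSE]
  ell <- sqrt(rowSums(seg^2))
  L <- sum(ell)
  if (L < root$zone_length)
    stop("centerline shorter than the elongation zone")
  cum <- c(0, cumsum(ell))                    # arc from base
  target <- (L - root$zone_length) + root$seg_len * (0:n)
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(ell)] <- length(ell)
  frac <- (target - cum[idx]) / ell[idx]
  new_centers <- centers[idx, , drop = FALSE] + frac * seg[idx, , drop = FALSE]
  rel <- relative_rotations(frames)
  new_frames <- array(0, dim = c(3L, 3L, n + 1L))
  for (i in seq_len(n + 1L)) {
    k <- idx[i]
    a <- rel$angle[k] * frac[i]
    if (abs(a) > 1e-14) {
      new_frames[, , i] <- frames[, , k] %*% rot3(rel$axis[k, ], a)
    } else {
      new_frames[, , i] <- frames[, , k]
    }
  }
  # freeze the basal leftover: old joints strictly below the new base
  drop_n <- sum(cum < target[1L] - 1e-12) # joints with arc < new base arc
  if (drop_n > 0L) {
    keep <- seq_len(drop_n)
    root$mature$centers <- rbind(root$mature$centers,
                                 centers[keep, , drop = FALSE])
    old <- root$mature$frames
    root$mature$frames <- array(c(old, frames[, , keep]),
                                dim = c(3L, 3L, dim(old)[3L] + drop_n))
  }
  root$centers <- new_centers
  root$frames <- new_frames
  root
}

#' Combined grow-and-resample step (compiled kernel)
#'
#' Equivalent to `resample_root(grow_step(root, ...))` but executed in one
#' compiled pass; this is what the simulation loop calls.  The split R
#' functions remain available and are used as an independent reference path
#' in the test suite.
#'
#' @inheritParams grow_step
#' @return The updated, resampled `root_state` (attribute `"extension"` as
#'   in [grow_step()]).
#' @export
step_root <- function(root, G_left, G_right, phi, dt) {
  out <- chain_step_cpp(root$centers, root$frames, G_left, G_right, phi,
                        dt, root$D, root$zone_length, root$seg_len)
  if (nrow(out$mature_centers) > 0L) {
    root$mature$centers <- rbind(root$mature$centers, out$mature_centers)
    old <- root$mature$frames
    root$mature$frames <- array(
      c(old, out$mature_frames),
      dim = c(3L, 3L, dim(old)[3L] + dim(out$mature_frames)[3L]))
  }
  root$centers <- out$centers
  root$frames <- out$frames
  attr(root, "extension") <- out$extension
  root
}

#' Report self-collision of the root centerline
#'
#' Checks whether any two non-adjacent portions of the centerline (frozen
#' mature trace plus active zone) approach closer than one diameter.
#' Detection is report-only: the growth model applies no collision
#' response, so slowly converging high-sensitivity roots can legitimately
#' self-intersect.
#'
#' @param root A `root_state`.
#' @param min_gap Number of intervening sections below which proximity is
#'   ignored (nearby sections along the chain are trivially close;
#'   default 15, i.e. 1.5 D of arc).
#' @return A list with `collided` (logical) and `min_distance` (smallest
#'   centerline separation between non-adjacent points, units of D).
#' @export
self_collision <- function(root, min_gap = 15L) {
  pts <- rbind(root$mature$centers, root$centers)
  m <- nrow(pts)
  if (m < 2L * min_gap)
    return(list(collided = FALSE, min_distance = Inf))
  best <- Inf
  for (i in seq_len(m - min_gap)) {
    rel <- pts[(i + min_gap):m, , drop = FALSE] -
      matrix(pts[i, ], m - i - min_gap + 1L, 3L, byrow = TRUE)
    best <- min(best, sqrt(min(rowSums(rel^2))))
  }
  list(collided = best < root$D - 1e-9, min_distance = best)
}
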