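# Thigmotropism: contact sensing through sensory points on the root cap,
# passive minimal-bending obstacle avoidance, and the inhibitory touch
# signal with configurable rise/decay memory.

#' Sensory points on the root cap
#'
#' Lays out tactile sensory points on the cap surface (`d < d_cap`): rings
#' of `n_ring` angularly equidistant points at `n_axial` axial stations,
#' plus the tip apex itself.  Points are expressed in world coordinates
#' using the local frames, at the surface radius given by [cap_radius()].
#'
#' @param root A `root_state`.
#' @param n_ring Points per ring (default 16).
#' @param n_axial Number of axial rings within the cap (default 8).
#' @param d_cap,p_cap Cap geometry parameters (see [cap_radius()]).
#' @return A list with `points` (m x 3), `d` (arc distance from tip of each
#'   point), `phi` (circumferential angle of each point).
#' @export
sensory_points <- function(root, n_ring = 16L, n_axial = 8L,
                           d_cap = 1.5, p_cap = 0.4) {
  dist <- joint_distances(root)
  m <- nrow(root$centers)
  # axial stations: rings equidistantly spaced in radius when seen from
  # the tip, i.e. at the cap radii r_i = 0.5 * i / n_axial, mapped back to
  # arc distances through the cap profile and snapped to the joints
  r_targets <- 0.5 * root$D * seq_len(n_axial) / n_axial
  d_targets <- d_cap * (r_targets / (0.5 * root$D))^(1 / p_cap)
  idx <- unique(vapply(d_targets, function(dt0)
    which.min(abs(dist - dt0)), integer(1)))
  idx <- idx[dist[idx] > 0 & dist[idx] <= d_cap]
  phis <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  cph <- cos(phis); sph <- sin(phis)
  pts <- matrix(0, length(idx) * n_ring + 1L, 3L)
  dd <- numeric(nrow(pts))
  pp <- numeric(nrow(pts))
  row <- 1L
  for (i in idx) {
    r <- cap_radius(dist[i], d_cap, p_cap, root$D)
    A <- root$frames[, , i]
    # u(phi) = sin(phi) x + cos(phi) y
    ring <- matrix(root$centers[i, ], n_ring, 3L, byrow = TRUE) +
      r * (outer(sph, A[, 1L]) + outer(cph, A[, 2L]))
    pts[row:(row + n_ring - 1L), ] <- ring
    dd[row:(row + n_ring - 1L)] <- dist[i]
    pp[row:(row + n_ring - 1L)] <- phis
    row <- row + n_ring
  }
  pts[row, ] <- root$centers[m, ]        # the apex
  dd[row] <- 0
  pp[row] <- 0
  list(points = pts, d = dd, phi = pp)
}

#' Detect root-obstacle contact
#'
#' Checks the sensory points against every obstacle; if any point lies
#' inside an obstacle, the contact is summarized by the mean of the
#' intersected points, expressed in root coordinates: arc distance `d_t`
#' from the tip, circumferential angle `phi_t` w.r.t. the reference curve,
#' cross-section radius `r_t`, and the estimated root-to-obstacle angle
#' `alpha_t` from [touch_angle()].
#'
#' @param root A `root_state`.
#' @param obstacles List of obstacles (see [obstacle_plane()]).
#' @param sensors Optional precomputed [sensory_points()].
#' @param p_cap Cap curvature exponent.
#' @param tol Contact tolerance: sensory points with clearance below `tol`
#'   count as touching.  `tol = 0` detects strict penetration (used by the
#'   passive correction); a small positive tolerance detects sustained
#'   sliding contact, where the corrected root rests just clear of the
#'   surface.
#' @return `NULL` if no contact, else a list of class `touch_event` with
#'   `mean_point`, `d_t`, `phi_t`, `r_t`, `alpha_t`, `depth` (maximum
#'   penetration depth; can be `<= 0` for grazing contact within `tol`),
#'   and `s_t = -2 * alpha_t / pi`.
#' @export
detect_contact <- function(root, obstacles, sensors = NULL, p_cap = 0.4,
                           tol = 0) {
  if (!length(obstacles)) return(NULL)
  if (is.null(sensors)) sensors <- sensory_points(root, p_cap = p_cap)
  clear <- rep(Inf, nrow(sensors$points))
  for (ob in obstacles)
    clear <- pmin(clear, signed_clearance(ob, sensors$points))
  hit <- clear < tol
  if (!any(hit)) return(NULL)
  mp <- colMeans(sensors$points[hit, , drop = FALSE])
  # locate the mean point on the root: project onto the centerline
  # (nearest joint plus the axial component in its frame), then the
  # circumferential angle w.r.t. the local reference direction
  rel <- root$centers - matrix(mp, nrow(root$centers), 3L, byrow = TRUE)
  i <- which.min(rowSums(rel^2))
  A <- root$frames[, , i]
  v <- mp - root$centers[i, ]
  d_t <- max(0, joint_distances(root)[i] - sum(A[, 3L] * v))
  px <- sum(A[, 1L] * v); py <- sum(A[, 2L] * v)
  phi_t <- if (px * px + py * py > 1e-24) atan2(px, py) else 0
  r_t <- cap_radius(d_t, p_cap = p_cap, D = root$D)
  a_t <- touch_angle(r_t, p_cap, D = root$D)
  structure(list(mean_point = mp, d_t = d_t, phi_t = phi_t, r_t = r_t,
                 alpha_t = a_t, depth = -min(clear),
                 s_t = -2 * a_t / pi),
            class = "touch_event")
}

#' Root-to-obstacle angle from the contact radius
#'
#' Estimates the angle between the root axis and the obstacle surface at
#' the contact cross-section.  The default `"profile"` method takes the
#' angle of the tangent to the actual cap profile [cap_radius()] at the
#' contact radius, `alpha_t = arctan(dr/dd)` with
#' `dr/dd = (0.5 * D * p_cap / d_cap) * (2 r_t / D)^((p_cap - 1)/p_cap)`;
#' this is the geometric contact angle, and it makes the touch and gravity
#' signals balance at a sliding angle of `90 * w_g / (w_g + w_t)` degrees
#' on a horizontal surface.  The `"power"` method is the compact power-law
#' form `alpha_t = arctan(p_cap * r_t^(p_cap - 1))`, which approximates
#' the same monotone decrease but is not the exact profile slope.  Contact
#' at the very tip (`r_t -> 0`) gives a head-on `alpha_t -> pi/2` in both.
#'
#' @param r_t Contact cross-section radius (units of D, `>= 0`).
#' @param p_cap Cap curvature exponent in (0, 1).
#' @param method `"profile"` (exact cap-profile slope; used by the
#'   simulation) or `"power"`.
#' @param d_cap,D Cap length and root diameter (profile method).
#' @return `alpha_t` in `(0, pi/2]`, radians (vectorized).
#' @export
touch_angle <- function(r_t, p_cap = 0.4, method = c("profile", "power"),
                        d_cap = 1.5, D = 1) {
  method <- match.arg(method)
  if (any(r_t < 0)) stop("'r_t' must be non-negative")
  if (p_cap <= 0 || p_cap >= 1) stop("'p_cap' must be in (0, 1)")
  slope <- if (method == "power") {
    p_cap * r_t^(p_cap - 1)
  } else {
    (0.5 * D * p_cap / d_cap) * (2 * r_t / D)^((p_cap - 1) / p_cap)
  }
  ifelse(r_t == 0, pi / 2, atan(slope))
}

# Pure bending of the chain: segment `j` bends by `theta[j]` at angle
# `phi` (no extension), tip-ward material carried rigidly.  Used by the
# passive thigmotropic correction (`theta` may be a scalar for uniform
# bending, or concentrated on a few basal sections).
bend_chain <- function(root, theta, phi) {
  n <- root$n
  theta <- rep_len(theta, n)
  c0 <- root$centers
  f0 <- root$frames
  centers <- c0
  frames <- f0
  sp <- sin(phi); cp <- cos(phi)
  for (j in seq_len(n)) {
    Ao <- f0[, , j]
    w <- as.vector(crossprod(Ao, c0[j + 1L, ] - c0[j, ]))
    Rrel <- crossprod(Ao, f0[, , j + 1L])
    Aj <- frames[, , j]
    if (theta[j] != 0) {
      M <- rot3(c(cp, -sp, 0), theta[j])
      centers[j + 1L, ] <- centers[j, ] + as.vector(Aj %*% (M %*% w))
      frames[, , j + 1L] <- ortho3(Aj %*% (M %*% Rrel))
    } else {
      centers[j + 1L, ] <- centers[j, ] + as.vector(Aj %*% w)
      frames[, , j + 1L] <- ortho3(Aj %*% Rrel)
    }
  }
  root$centers <- centers
  root$frames <- frames
  root
}

#' Passive minimal-bending obstacle correction
#'
#' While any sensory point penetrates an obstacle, applies a small bend at
#' the contact angle `phi_t` (curving the root away from the obstacle) and
#' re-checks, so the total applied bend is minimal up to the iteration
#' step size.  The root can touch obstacles but never rests inside one.
#' In the default `"base"` mode each iteration bends the most basal
#' sections of the elongation zone -- the longest lever, hence the
#' smallest total bend that clears the obstacle, leaving the apex free to
#' hold its stimulus-driven orientation while sliding.  `"uniform"`
#' distributes the same per-iteration bend over every section.
#'
#' @param root A `root_state`.
#' @param obstacles List of obstacles.
#' @param step Bend angle per iteration (radians; per section in
#'   `"uniform"` mode, total in `"base"` mode).
#' @param max_iter Iteration cap; if reached the root is flagged trapped
#'   and returned as corrected so far.
#' @param p_cap Cap curvature exponent.
#' @param mode `"base"` (default) or `"uniform"`.
#' @return The corrected `root_state`; attributes `"iterations"` and
#'   `"trapped"` report the outcome.
#' @export
passive_correction <- function(root, obstacles, step = 2e-3,
                               max_iter = 500L, p_cap = 0.4,
                               mode = c("base", "uniform")) {
  mode <- match.arg(mode)
  n <- root$n
  theta <- if (mode == "base") {
    # spread the per-iteration bend over the basal 5 sections
    c(rep(step / 5, 5L), rep(0, n - 5L))
  } else step
  it <- 0L
  trapped <- FALSE
  repeat {
    ev <- detect_contact(root, obstacles, p_cap = p_cap, tol = 0)
    if (is.null(ev) || ev$depth <= 0) break
    if (it >= max_iter) { trapped <- TRUE; break }
    root <- bend_chain(root, theta, ev$phi_t)
    it <- it + 1L
  }
  attr(root, "iterations") <- it
  attr(root, "trapped") <- trapped
  root
}

#' Touch-signal memory update
#'
#' One leaky step of the filtered inhibitory touch signal.  During contact
#' the state relaxes toward `-2 * alpha_t / pi` with time constant
#' `tau_rise`; after contact loss it relaxes toward 0 with `tau_decay`.
#' `tau = dt` makes the corresponding transition immediate; the
#' asymmetric-memory regime uses `tau_rise = dt`, `tau_decay = 10` hours
#' (immediate inhibition, slow forgetting).
#'
#' @param state Current filtered strength (scalar, `<= 0`).
#' @param event A `touch_event` or `NULL` (no contact).
#' @param dt Time step (hours).
#' @param tau_rise,tau_decay Time constants (hours, `>= dt`).
#' @return The updated strength.
#' @export
touch_signal_step <- function(state, event, dt, tau_rise = dt,
                              tau_decay = dt) {
  if (tau_rise < dt || tau_decay < dt) stop("touch tau must be >= dt")
  if (!is.null(event)) {
    state + (dt / tau_rise) * (event$s_t - state)
  } else {
    state + (dt / tau_decay) * (0 - state)
  }
}
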