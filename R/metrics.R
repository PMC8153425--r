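# Quantification of circumnutation movements and gradient-climbing
# performance from simulation traces.

#' Extrema of the one-side growth-rate series
#'
#' Detects local minima and maxima of the (normalized) growth rate sampled
#' on one side of the root over time -- the instants of maximal
#' differential growth, i.e. the turning points of a circumnutation cycle.
#' A 3-point local comparison is used with a minimum-prominence threshold
#' (a fraction of the series range) to suppress numerical ripple;
#' detections are reduced to a strictly alternating min/max sequence,
#' keeping the most extreme sample of any same-type run.
#'
#' @param x Numeric series (length >= 3).
#' @param times Optional sample times (defaults to `seq_along(x)`).
#' @param prominence Minimum peak-to-neighbour-valley excursion, as a
#'   fraction of `diff(range(x))` (default 0.01).
#' @return A data frame with columns `index`, `t`, `value`, `type`
#'   (+1 max, -1 min); zero rows if the series is monotone or flat.
#' @export
nutation_extrema <- function(x, times = seq_along(x), prominence = 0.01) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), t = numeric(),
                                value = numeric(), type = integer()))
  rng <- diff(range(x))
  if (rng <= 0) return(data.frame(index = integer(), t = numeric(),
                                  value = numeric(), type = integer()))
  mid <- 2:(n - 1L)
  is_max <- x[mid] > x[mid - 1L] & x[mid] >= x[mid + 1L]
  is_min <- x[mid] < x[mid - 1L] & x[mid] <= x[mid + 1L]
  idx <- mid[is_max | is_min]
  if (!length(idx)) return(data.frame(index = integer(), t = numeric(),
                                      value = numeric(), type = integer()))
  type <- ifelse(is_max[match(idx, mid)], 1L, -1L)
  # enforce alternation, then prune shallow neighbouring pairs
  keep_idx <- idx[1L]; keep_type <- type[1L]
  for (k in seq_along(idx)[-1L]) {
    last <- length(keep_idx)
    if (type[k] == keep_type[last]) {
      better <- (type[k] == 1L && x[idx[k]] > x[keep_idx[last]]) ||
        (type[k] == -1L && x[idx[k]] < x[keep_idx[last]])
      if (better) keep_idx[last] <- idx[k]
    } else {
      keep_idx <- c(keep_idx, idx[k])
      keep_type <- c(keep_type, type[k])
    }
  }
  # prominence pruning: drop the shallowest adjacent pair until all
  # consecutive excursions clear the threshold
  thr <- prominence * rng
  repeat {
    if (length(keep_idx) < 2L) break
    exc <- abs(diff(x[keep_idx]))
    small <- which(exc < thr)
    if (!length(small)) break
    k <- small[which.min(exc[small])]
    drop <- if (k == 1L) k else k + 1L
    keep_idx <- keep_idx[-drop]
    keep_type <- keep_type[-drop]
    # re-merge equal-type neighbours created by the deletion
    k2 <- 2L
    while (k2 <= length(keep_idx)) {
      if (keep_type[k2] == keep_type[k2 - 1L]) {
        better <- (keep_type[k2] == 1L &&
                     x[keep_idx[k2]] > x[keep_idx[k2 - 1L]]) ||
          (keep_type[k2] == -1L && x[keep_idx[k2]] < x[keep_idx[k2 - 1L]])
        rm_at <- if (better) k2 - 1L else k2
        keep_idx <- keep_idx[-rm_at]
        keep_type <- keep_type[-rm_at]
      } else k2 <- k2 + 1L
    }
  }
  data.frame(index = keep_idx, t = times[keep_idx], value = x[keep_idx],
             type = keep_type)
}

#' Periods, amplitudes, and cycle count from extrema
#'
#' Given the turning points of the growth-rate series mapped to tip
#' positions, estimates: the amplitude of each cycle from consecutive
#' position triples `p1, p2, p3` as `|| (p1 + p3)/2 - p2 ||` (distance of
#' the middle turning point from the midpoint of its neighbours); the
#' period as the time between consecutive same-type extrema (one full
#' cycle); and the number of complete cycles.
#'
#' @param extrema Data frame from [nutation_extrema()].
#' @param positions Matrix (rows matching `extrema$index`) of tip positions
#'   at the extrema; if omitted, amplitudes are skipped.
#' @return A list of class `nutation_metrics`: `n_extrema`, `n_cycles`,
#'   `periods`, `amplitudes`, `median_period`, `median_amplitude`.
#' @export
nutation_period_amplitude <- function(extrema, positions = NULL) {
  m <- nrow(extrema)
  periods <- numeric(0)
  amplitudes <- numeric(0)
  if (m >= 3L) {
    for (tp in c(-1L, 1L)) {
      tt <- extrema$t[extrema$type == tp]
      if (length(tt) >= 2L) periods <- c(periods, diff(tt))
    }
    periods <- sort(periods)
    if (!is.null(positions) && nrow(positions) == m) {
      for (k in 1:(m - 2L)) {
        p1 <- positions[k, ]; p2 <- positions[k + 1L, ]; p3 <- positions[k + 2L, ]
        amplitudes <- c(amplitudes, sqrt(sum(((p1 + p3) / 2 - p2)^2)))
      }
    }
  }
  n_cycles <- as.integer(max(0, floor((m - 1) / 2)))
  structure(list(n_extrema = m, n_cycles = n_cycles, periods = periods,
                 amplitudes = amplitudes,
                 median_period = if (length(periods)) stats::median(periods) else NA_real_,
                 median_amplitude = if (length(amplitudes)) stats::median(amplitudes) else NA_real_),
            class = "nutation_metrics")
}

#' Gradient-climbing performance score
#'
#' Normalized concentration gain over a run relative to the best
#' achievable gain: `f = (C_end - C_start) / (C_best - C_start)`, clipped
#' to `[-1, 1]`.  `f = 1` when the run matches the best possible final
#' concentration, 0 when nothing was gained, negative when the root grew
#' down-gradient.
#'
#' @param C_start,C_end Tip concentration at the start and end of the run.
#' @param C_best Best achievable final concentration (see
#'   [best_concentration()]).
#' @return `f` in `[-1, 1]`.
#' @export
performance_f <- function(C_start, C_end, C_best) {
  if (any(C_best <= C_start)) stop("'C_best' must exceed 'C_start'")
  pmin(1, pmax(-1, (C_end - C_start) / (C_best - C_start)))
}

#' Best achievable final concentration
#'
#' The concentration at the point reached by growing straight up the local
#' gradient at the baseline rate for the whole duration, clipped to the
#' field bounds.  Used as the reference `C*` in [performance_f()].
#'
#' @param field A [resource_field()].
#' @param start Tip start position (3-vector).
#' @param duration Run duration (hours).
#' @param G_base Baseline growth rate (D/hour).
#' @return The reference concentration `C*`.
#' @export
best_concentration <- function(field, start, duration, G_base = 1) {
  dir <- switch(field$kind,
    uniform = c(0, 0, 0),
    linear = field$direction,
    radial = {
      v <- field$center - start
      nv <- sqrt(sum(v^2))
      if (nv > 0) v / nv else c(0, 0, 0)
    })
  concentration(field, start + duration * G_base * dir)
}

#' Angle between the root tip and an obstacle surface
#'
#' @param root A `root_state`.
#' @param obstacle A plane obstacle.
#' @return Angle in degrees between the tip tangent and the obstacle
#'   surface plane (0 = sliding parallel, 90 = head-on).
#' @export
tip_obstacle_angle <- function(root, obstacle) {
  if (obstacle$kind != "plane") stop("angle defined for plane obstacles")
  z <- tip_frame(root)[, 3L]
  asin(pmin(1, abs(sum(z * obstacle$normal)))) * 180 / pi
}
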