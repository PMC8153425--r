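# print / summary / plot methods for the simulation result classes.

#' @export
print.root_sim <- function(x, ...) {
  p <- x$params
  cat("Root growth simulation (", p$dim, "-D)\n", sep = "")
  cat("  duration: ", p$duration, " h,  dt = ", p$dt, " h\n", sep = "")
  active <- c(gravity = p$w_g, touch = p$w_t, resource = p$w_s)
  active <- active[active != 0]
  cat("  stimuli:  ",
      if (length(active)) paste(names(active), "=", active, collapse = ", ")
      else "none (baseline growth)", "\n", sep = "")
  tp <- utils::tail(x$trace, 1L)
  cat(sprintf("  final tip: (%.2f, %.2f, %.2f) D,  angle to gravity %.1f deg\n",
              tp$x, tp$y, tp$z, tp$tip_angle))
  if (!is.na(tp$C)) cat(sprintf("  tip concentration: %.3f\n", tp$C))
  invisible(x)
}

#' @export
summary.root_sim <- function(object, ...) {
  m <- nutation_metrics(object)
  tr <- object$trace
  out <- list(params = object$params, metrics = m,
              final = utils::tail(tr, 1L),
              total_growth = nrow(object$root$mature$centers) *
                object$root$seg_len + object$root$zone_length,
              contact_fraction = mean(tr$contact, na.rm = TRUE))
  class(out) <- "summary.root_sim"
  out
}

#' @export
print.summary.root_sim <- function(x, ...) {
  cat("Circumnutation metrics:\n")
  cat("  extrema: ", x$metrics$n_extrema,
      ",  complete cycles: ", x$metrics$n_cycles, "\n", sep = "")
  if (!is.na(x$metrics$median_period))
    cat(sprintf("  median period: %.2f h,  median amplitude: %.3f D\n",
                x$metrics$median_period, x$metrics$median_amplitude))
  cat(sprintf("Final tip angle to gravity: %.2f deg\n", x$final$tip_angle))
  if (!is.na(x$final$C))
    cat(sprintf("Final tip concentration: %.3f\n", x$final$C))
  if (!is.nan(x$contact_fraction) && x$contact_fraction > 0)
    cat(sprintf("Obstacle contact fraction: %.2f\n", x$contact_fraction))
  invisible(x)
}

#' Plot a simulated root
#'
#' Draws the tip trajectory and the final root centerline projected on a
#' coordinate plane.
#'
#' @param x A `root_sim`.
#' @param plane Projection plane: `"xz"` (default), `"xy"`, or `"yz"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.root_sim <- function(x, plane = c("xz", "xy", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1L]]
  cols <- match(ax, c("x", "y", "z"))
  tr <- x$trace
  tip <- cbind(tr$x, tr$y, tr$z)[, cols, drop = FALSE]
  body <- root_polyline(x$root)[, cols, drop = FALSE]
  rng1 <- range(tip[, 1L], body[, 1L])
  rng2 <- range(tip[, 2L], body[, 2L])
  graphics::plot(NA, xlim = rng1, ylim = rng2, xlab = ax[1L],
                 ylab = ax[2L], asp = 1, ...)
  graphics::lines(body, lwd = 3, col = "grey40")
  graphics::lines(tip, col = "magenta")
  invisible(x)
}

#' @export
print.gravitropic_sweep <- function(x, ...) {
  cat("Gravitropic sweep:", nrow(x$runs), "runs\n")
  print(x$runs, digits = 3)
  if (!is.na(x$amplitude_ratio))
    cat(sprintf("\nDifferential-growth amplitude ratio (distal/proximal peak): %.3f\n",
                x$amplitude_ratio))
  if (!is.null(x$rank_test))
    cat(sprintf("Rank-sum test p-value: %.3g\n", x$rank_test$p.value))
  invisible(x)
}

#' @export
print.gradient_study <- function(x, ...) {
  cat("Randomized gradient-climbing study:", nrow(x$runs), "runs\n")
  cat("Median performance f by group:\n")
  print(round(x$groups, 4))
  cat("Runs with >= 1 circumnutation cycle:", x$n_cycling, "\n")
  invisible(x)
}

#' @export
print.specialization_run <- function(x, ...) {
  cat("Multi-root specialization:", length(x$sims), "roots\n")
  for (nm in names(x$sims)) {
    tp <- utils::tail(x$sims[[nm]]$trace, 1L)
    cat(sprintf("  %-8s tip (%.1f, %.1f, %.1f)  C = %.3f\n",
                nm, tp$x, tp$y, tp$z, tp$C))
  }
  invisible(x)
}

#' @export
print.nutation_metrics <- function(x, ...) {
  cat("Nutation metrics: ", x$n_extrema, " extrema, ", x$n_cycles,
      " cycles\n", sep = "")
  if (!is.na(x$median_period))
    cat(sprintf("  median period %.2f h, median amplitude %.3f D\n",
                x$median_period, x$median_amplitude))
  invisible(x)
}
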