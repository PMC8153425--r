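# Trace, snapshot, metrics, and mesh export.

#' Write a root snapshot as CSV
#'
#' One row per cross-section (frozen mature trace first, then the active
#' elongation zone): time, section index, arc distance from the tip,
#' center coordinates, radius, and the nine frame entries (row-major).
#'
#' @param sim A `root_sim` (or a bare `root_state`).
#' @param file Output path.
#' @param d_cap,p_cap Cap profile for the radii.
#' @return The written data frame, invisibly.
#' @export
write_root_snapshot <- function(sim, file, d_cap = 1.5, p_cap = 0.4) {
  root <- if (inherits(sim, "root_sim")) sim$root else sim
  t <- if (inherits(sim, "root_sim")) utils::tail(sim$trace$t, 1L) else root$t
  centers <- rbind(root$mature$centers, root$centers)
  nm <- nrow(root$mature$centers)
  frames <- array(c(root$mature$frames, root$frames),
                  dim = c(3L, 3L, nrow(centers)))
  d <- c(rep(root$zone_length, nm) + root$seg_len * (nm:1L)[seq_len(nm)],
         joint_distances(root))
  fr <- t(apply(frames, 3L, function(A) as.vector(t(A))))
  colnames(fr) <- paste0("a", rep(1:3, each = 3L), rep(1:3, 3L))
  out <- data.frame(t = t, section_index = seq_len(nrow(centers)), d = d,
                    cx = centers[, 1L], cy = centers[, 2L],
                    cz = centers[, 3L],
                    radius = cap_radius(d, d_cap, p_cap, root$D))
  out <- cbind(out, fr)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Write the tip trajectory as CSV
#'
#' @param sim A `root_sim`.
#' @param file Output path.
#' @return The written data frame, invisibly.
#' @export
write_tip_trajectory <- function(sim, file) {
  out <- sim$trace[, c("t", "x", "y", "z")]
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Write the obstacle-contact log as CSV
#'
#' One row per simulation step with obstacle contact: time, contact
#' location in root coordinates (arc distance, circumferential angle),
#' estimated contact angle, and the emitted touch strength.
#'
#' @param sim A `root_sim` from a run with obstacles.
#' @param file Output path.
#' @return The written data frame, invisibly.
#' @export
write_contact_log <- function(sim, file) {
  tr <- sim$trace
  out <- tr[tr$contact > 0, c("t", "d_t", "phi_t", "alpha_t", "s_t")]
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Write per-run metrics as CSV
#'
#' @param sims A named list of `root_sim` objects (or a single one).
#' @param file Output path.
#' @return The written data frame, invisibly.
#' @export
write_metrics_csv <- function(sims, file) {
  if (inherits(sims, "root_sim")) sims <- list(run = sims)
  rows <- lapply(names(sims), function(nm) {
    m <- nutation_metrics(sims[[nm]])
    tp <- utils::tail(sims[[nm]]$trace, 1L)
    data.frame(run_id = nm, n_cycles = m$n_cycles,
               median_period = m$median_period,
               median_amplitude = m$median_amplitude,
               final_tip_angle = tp$tip_angle, final_C = tp$C)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Export the root surface as a Wavefront OBJ mesh
#'
#' Projects `n_circ` circumference points at the local radius around every
#' cross-section and connects consecutive rings with quads.
#'
#' @param sim A `root_sim` or `root_state`.
#' @param file Output path.
#' @param n_circ Points per circumference ring.
#' @param d_cap,p_cap Cap profile parameters.
#' @return Invisibly, the vertex count.
#' @export
export_obj <- function(sim, file, n_circ = 16L, d_cap = 1.5, p_cap = 0.4) {
  root <- if (inherits(sim, "root_sim")) sim$root else sim
  centers <- rbind(root$mature$centers, root$centers)
  frames <- array(c(root$mature$frames, root$frames),
                  dim = c(3L, 3L, nrow(centers)))
  nm <- nrow(root$mature$centers)
  d <- c(rep(root$zone_length, nm) + root$seg_len * (nm:1L)[seq_len(nm)],
         joint_distances(root))
  phis <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  m <- nrow(centers)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# root surface mesh", con)
  for (i in seq_len(m)) {
    r <- cap_radius(d[i], d_cap, p_cap, root$D)
    A <- frames[, , i]
    ring <- matrix(centers[i, ], n_circ, 3L, byrow = TRUE) +
      r * (outer(sin(phis), A[, 1L]) + outer(cos(phis), A[, 2L]))
    writeLines(sprintf("v %.6f %.6f %.6f", ring[, 1L], ring[, 2L],
                       ring[, 3L]), con)
  }
  for (i in seq_len(m - 1L)) {
    b0 <- (i - 1L) * n_circ
    for (j in seq_len(n_circ)) {
      j2 <- if (j == n_circ) 1L else j + 1L
      writeLines(sprintf("f %d %d %d %d", b0 + j, b0 + j2,
                         b0 + n_circ + j2, b0 + n_circ + j), con)
    }
  }
  invisible(m * n_circ)
}

#' Write recorded growth surfaces as a long CSV
#'
#' Requires a run with `record_surfaces = TRUE`: writes rows
#' `(t, d, phi, G_b, S_a, G_s)` for every recorded step.
#'
#' @param sim A `root_sim` simulated with `record_surfaces = TRUE`.
#' @param file Output path.
#' @param d_grid,phi_grid Optional grids (defaults reconstructed from the
#'   run parameters).
#' @return Invisibly, the number of rows written.
#' @export
write_surface_dump <- function(sim, file, d_grid = NULL, phi_grid = NULL) {
  if (is.null(sim$surfaces)) stop("run with record_surfaces = TRUE")
  p <- sim$params
  n <- round(p$zone_length / (p$dt * p$G_base))
  if (is.null(d_grid))
    d_grid <- p$zone_length - (seq_len(n) - 1L) * p$zone_length / n
  if (is.null(phi_grid))
    phi_grid <- if (p$dim == 2) c(0, pi) else
      seq(-pi, pi, length.out = p$n_phi)
  G_b <- baseline_surface(d_grid, p$peak_d, p$zone_length, p$G_base)
  first <- TRUE
  nrows <- 0L
  for (srf in sim$surfaces) {
    df <- data.frame(t = srf$t,
                     d = rep(d_grid, times = length(phi_grid)),
                     phi = rep(phi_grid, each = length(d_grid)),
                     G_b = rep(G_b, times = length(phi_grid)),
                     S_a = as.vector(srf$S_a),
                     G_s = as.vector(srf$G_s))
    utils::write.table(df, file, sep = ",", row.names = FALSE,
                       col.names = first, append = !first)
    first <- FALSE
    nrows <- nrows + nrow(df)
  }
  invisible(nrows)
}
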