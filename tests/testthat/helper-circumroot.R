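# Shared fixtures: all built in code at test time.

# Per-segment baseline rates on the default 60-segment grid.
default_gb <- function(peak = 3, zone = 6) {
  baseline_surface(zone - (seq_len(round(zone / 0.1)) - 1L) * 0.1,
                   peak_d = peak, zone_length = zone)
}

# A straight horizontal root with default discretization.
horizontal_root <- function() root_state(direction = c(1, 0, 0))

# Max orthonormality defect over all frames of a root state.
max_frame_defect <- function(root) {
  m <- dim(root$frames)[3L]
  max(vapply(seq_len(m), function(i) {
    A <- root$frames[, , i]
    max(max(abs(crossprod(A) - diag(3))), abs(det(A) - 1))
  }, numeric(1)))
}

# Linear resource field rising along +x, C = 0.5 at the origin.
linear_field_env <- function(slope = 0.05) {
  root_environment(field = resource_field(
    "linear", C0 = 0.5, slope = slope,
    origin = c(0, 0, 0), direction = c(1, 0, 0)))
}

# Horizontal floor at z = 0 (free space above).
floor_env <- function() {
  root_environment(obstacles = list(
    obstacle_plane(point = c(0, 0, 0), normal = c(0, 0, 1))))
}
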