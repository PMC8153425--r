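# Environment: gravity vector, obstacle primitives with exact signed
# clearances, and scalar resource-concentration fields.

#' Scalar resource-concentration fields
#'
#' Constructs a resource field `C(x)` with values clipped to `[0, 1]`.
#' Three kinds are supported: `"uniform"` (constant), `"linear"`
#' (`C0 + slope * <x - origin, direction>`, e.g. a horizontal nutrient
#' gradient rising by `slope` per diameter of displacement), and
#' `"radial"` (`Cmax - slope * |x - center|`, peaking at `center`).
#'
#' @param kind One of `"uniform"`, `"linear"`, `"radial"`.
#' @param C0 Base concentration (uniform value, or the linear field's value
#'   at `origin`).
#' @param slope Concentration change per unit distance (1/D).
#' @param origin,direction Linear field anchor point and gradient direction
#'   (direction is normalized internally).
#' @param center,Cmax Radial field peak location and peak value.
#' @return An object of class `resource_field`.
#' @export
resource_field <- function(kind = c("uniform", "linear", "radial"),
                           C0 = 0.5, slope = 0.05,
                           origin = c(0, 0, 0), direction = c(1, 0, 0),
                           center = c(0, 0, 0), Cmax = 1) {
  kind <- match.arg(kind)
  dir <- direction / sqrt(sum(direction^2))
  structure(list(kind = kind, C0 = C0, slope = slope, origin = origin,
                 direction = dir, center = center, Cmax = Cmax),
            class = "resource_field")
}

#' Evaluate a resource field at points
#'
#' Pure, deterministic point evaluation with clipping to `[0, 1]`.
#'
#' @param field A [resource_field()].
#' @param x A 3-vector or an m x 3 matrix of positions.
#' @return Concentration value(s) in `[0, 1]`.
#' @export
concentration <- function(field, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, 3L)
  v <- switch(field$kind,
    uniform = rep(field$C0, nrow(x)),
    linear = field$C0 +
      field$slope * as.vector((x - matrix(field$origin, nrow(x), 3L,
                                          byrow = TRUE)) %*% field$direction),
    radial = field$Cmax -
      field$slope * sqrt(rowSums((x - matrix(field$center, nrow(x), 3L,
                                             byrow = TRUE))^2)))
  pmin(1, pmax(0, v))
}

#' Obstacle primitives
#'
#' `obstacle_plane()` is the half-space on the side opposite to `normal`
#' (points with `<x - point, normal> < 0` are inside the obstacle);
#' `obstacle_box()` is a solid axis-aligned box; `obstacle_chain()` is a
#' capsule chain of radius `radius` around a polyline (used for root-root
#' contact in multi-root scenarios).
#'
#' @param point A point on the plane surface.
#' @param normal Outward normal (free space is on the `+normal` side);
#'   normalized internally.
#' @param lo,hi Box corner coordinates (3-vectors, `lo < hi`).
#' @param points m x 3 polyline vertices.
#' @param radius Capsule radius (units of D).
#' @return An object of class `obstacle`.
#' @export
obstacle_plane <- function(point = c(0, 0, 0), normal = c(0, 0, 1)) {
  n <- normal / sqrt(sum(normal^2))
  structure(list(kind = "plane", point = point, normal = n),
            class = "obstacle")
}

#' @rdname obstacle_plane
#' @export
obstacle_box <- function(lo, hi) {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(lo < hi))
  structure(list(kind = "box", lo = lo, hi = hi), class = "obstacle")
}

#' @rdname obstacle_plane
#' @export
obstacle_chain <- function(points, radius = 0.5) {
  structure(list(kind = "chain", points = points, radius = radius),
            class = "obstacle")
}

#' Signed clearance from an obstacle
#'
#' Exact signed distance to the obstacle surface: positive outside (free),
#' negative inside.
#'
#' @param obstacle An [obstacle_plane()], [obstacle_box()], or
#'   [obstacle_chain()].
#' @param x A 3-vector or m x 3 matrix of query points.
#' @return Signed distance(s).
#' @export
signed_clearance <- function(obstacle, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, 3L)
  switch(obstacle$kind,
    plane = as.vector((x - matrix(obstacle$point, nrow(x), 3L,
                                  byrow = TRUE)) %*% obstacle$normal),
    box = {
      qlo <- matrix(obstacle$lo, nrow(x), 3L, byrow = TRUE) - x
      qhi <- x - matrix(obstacle$hi, nrow(x), 3L, byrow = TRUE)
      q <- pmax(qlo, qhi)                       # per-axis outside distance
      inside <- pmax(q[, 1L], pmax(q[, 2L], q[, 3L]))
      qp <- q; qp[qp < 0] <- 0
      outside <- sqrt(rowSums(qp^2))
      ifelse(inside < 0, inside, outside)
    },
    chain = point_chain_distance(x, obstacle$points) - obstacle$radius)
}

# Minimum distance from each query point to a polyline (segment chain).
point_chain_distance <- function(x, pts) {
  m <- nrow(pts)
  if (m == 1L)
    return(sqrt(rowSums((x - matrix(pts[1L, ], nrow(x), 3L, byrow = TRUE))^2)))
  best <- rep(Inf, nrow(x))
  a <- pts[-m, , drop = FALSE]
  seg <- pts[-1L, , drop = FALSE] - a
  len2 <- rowSums(seg^2)
  for (k in seq_len(m - 1L)) {
    rel <- x - matrix(a[k, ], nrow(x), 3L, byrow = TRUE)
    tt <- (rel %*% seg[k, ]) / max(len2[k], 1e-300)
    tt <- pmin(1, pmax(0, as.vector(tt)))
    dd <- rel - outer(tt, seg[k, ])
    best <- pmin(best, rowSums(dd^2))
  }
  sqrt(best)
}

#' Environment specification
#'
#' Bundles the gravity direction, the obstacle set, and an optional
#' resource field.
#'
#' @param gravity Gravity direction (3-vector, default `c(0, 0, -1)`; only
#'   the direction is used).
#' @param obstacles A list of [obstacle_plane()] / [obstacle_box()] objects.
#' @param field An optional [resource_field()].
#' @return An object of class `root_environment`.
#' @export
root_environment <- function(gravity = c(0, 0, -1), obstacles = list(),
                             field = NULL) {
  structure(list(gravity = gravity / sqrt(sum(gravity^2)),
                 obstacles = obstacles, field = field),
            class = "root_environment")
}

#' Serialize or restore an environment as JSON
#'
#' @param env A [root_environment()].
#' @param txt JSON text produced by `environment_to_json()`.
#' @return `environment_to_json()`: a JSON string; `environment_from_json()`:
#'   a `root_environment`.
#' @export
environment_to_json <- function(env) {
  jsonlite::toJSON(unclass_deep(env), auto_unbox = FALSE, digits = NA)
}

#' @rdname environment_to_json
#' @export
environment_from_json <- function(txt) {
  raw <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  raw <- rapply(raw, unlist, how = "replace")
  obstacles <- lapply(raw$obstacles, function(o) {
    switch(o$kind,
      plane = obstacle_plane(o$point, o$normal),
      box = obstacle_box(o$lo, o$hi),
      chain = obstacle_chain(matrix(unlist(o$points), ncol = 3L), o$radius),
      stop("unknown obstacle kind: ", o$kind))
  })
  field <- if (!is.null(raw$field) && length(raw$field)) {
    resource_field(kind = raw$field$kind, C0 = raw$field$C0,
                   slope = raw$field$slope, origin = raw$field$origin,
                   direction = raw$field$direction, center = raw$field$center,
                   Cmax = raw$field$Cmax)
  }
  root_environment(gravity = raw$gravity, obstacles = obstacles,
                   field = field)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
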