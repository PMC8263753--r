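# Small geometric helpers shared across modules. All coordinates are physical
# micrometres in a right-handed frame unless stated otherwise.

vec_norm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Construct a plane from a point and a normal
#'
#' Planes carry a base point and a unit normal. By convention the positive
#' side of valve planes is the arterial (STJ) side.
#'
#' @param point numeric 3-vector on the plane (um).
#' @param normal numeric 3-vector; normalized internally.
#' @return An object of class `valve_plane`.
#' @export
valve_plane <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unitize(as.numeric(normal))),
            class = "valve_plane")
}

#' Signed distance from points to a plane
#'
#' @param plane a [valve_plane()].
#' @param pts numeric 3-vector or n x 3 matrix (um).
#' @return Signed distances (um); positive on the side the normal points to.
#' @export
plane_distance <- function(plane, pts) {
  pts <- rbind3(pts)
  drop((pts - matrix(plane$point, nrow(pts), 3, byrow = TRUE)) %*% plane$normal)
}

# coerce a 3-vector or n x 3 matrix to matrix form
rbind3 <- function(pts) {
  if (is.null(dim(pts))) matrix(as.numeric(pts), 1, 3) else as.matrix(pts)
}

#' Plane through three points
#'
#' @param p1,p2,p3 numeric 3-vectors (um).
#' @param orient_towards optional point; the normal is flipped so this point
#'   lies on the positive side.
#' @return A [valve_plane()].
#' @export
plane_through_points <- function(p1, p2, p3, orient_towards = NULL) {
  n <- cross3(p2 - p1, p3 - p1)
  if (vec_norm(n) < 1e-9 * max(vec_norm(p2 - p1), vec_norm(p3 - p1), 1)) {
    stop("degenerate plane: the three defining points are (near-)collinear")
  }
  pl <- valve_plane(p1, n)
  if (!is.null(orient_towards) && plane_distance(pl, orient_towards) < 0) {
    pl$normal <- -pl$normal
  }
  pl
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthogonal projection of points onto a plane
project_onto_plane <- function(plane, pts) {
  pts <- rbind3(pts)
  d <- plane_distance(plane, pts)
  pts - outer(d, plane$normal)
}

# Deterministic right-handed orthonormal frame (e1, e2, n) with third axis n.
frame_from_normal <- function(n) {
  n <- unitize(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(ref, n))
  e2 <- cross3(n, e1)
  cbind(e1, e2, n)
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- unitize(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# cumulative chord length of an ordered polyline (n x 3)
polyline_cumlen <- function(pts) {
  pts <- rbind3(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

polyline_length <- function(pts) {
  cl <- polyline_cumlen(pts)
  cl[length(cl)]
}

# point at a given fraction of total arc length along a polyline
polyline_point_at <- function(pts, frac) {
  pts <- rbind3(pts)
  cl <- polyline_cumlen(pts)
  target <- frac * cl[length(cl)]
  c(approx(cl, pts[, 1], xout = target, ties = "ordered")$y,
    approx(cl, pts[, 2], xout = target, ties = "ordered")$y,
    approx(cl, pts[, 3], xout = target, ties = "ordered")$y)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# decimate an ordered polyline to approximately `spacing` um between nodes,
# always keeping both endpoints
decimate_polyline <- function(pts, spacing) {
  pts <- rbind3(pts)
  cl <- polyline_cumlen(pts)
  total <- cl[length(cl)]
  if (total <= spacing) return(pts[c(1, nrow(pts)), , drop = FALSE])
  nseg <- max(3, ceiling(total / spacing))
  keep <- vapply(seq(0, total, length.out = nseg + 1),
                 function(t) which.min(abs(cl - t)), integer(1))
  pts[unique(keep), , drop = FALSE]
}
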