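# Geometric tolerance defaults; every user-facing tolerance can be overridden
# per call, these are the package-wide constants.
.tmj_tol <- list(
  geom = 1e-9,     # unit-normal / residual tolerance (mm)
  area = 1e-9      # minimum triangle area for non-degeneracy (mm^2)
)

#' Package tolerances
#'
#' Returns the package's geometric tolerance constants. Individual functions
#' accept a `tol` argument to override them per call.
#'
#' @return Named list with elements `geom` (residual/unit-length tolerance, mm)
#'   and `area` (minimum triangle area treated as non-degenerate, mm^2).
#' @export
tmj_tolerances <- function() .tmj_tol

.as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop(sprintf("'%s' must be a finite numeric xyz triple", what),
         call. = FALSE)
  }
  p
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v, what = "vector") {
  n <- .norm3(v)
  if (!is.finite(n) || n < .tmj_tol$geom) {
    stop(sprintf("degenerate geometry: cannot normalise %s (norm %g)",
                 what, n), call. = FALSE)
  }
  v / n
}

#' Oriented plane in 3D
#'
#' A plane is stored as a unit normal plus one point on the plane; the stored
#' normal orientation fixes the sign convention of [signed_distance()].
#'
#' @param normal Numeric xyz; normalised internally (must be nonzero).
#' @param point Numeric xyz on the plane (mm).
#' @return An object of class `tmj_plane` with fields `normal` and `point`.
#' @export
plane <- function(normal, point) {
  n <- .unit3(.as_point3(normal, "normal"), "plane normal")
  structure(list(normal = n, point = .as_point3(point)), class = "tmj_plane")
}

#' @export
print.tmj_plane <- function(x, ...) {
  cat(sprintf("<plane> n = (%.6f, %.6f, %.6f), through (%.3f, %.3f, %.3f)\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$point[1], x$point[2], x$point[3]))
  invisible(x)
}

#' Plane through three points
#'
#' The normal is the normalised cross product `(p2 - p1) x (p3 - p1)`, so the
#' stored orientation follows the right-hand rule on the argument order.
#'
#' @param p1,p2,p3 Numeric xyz points (mm); must not be collinear.
#' @return A [plane()].
#' @export
plane_from_three_points <- function(p1, p2, p3) {
  p1 <- .as_point3(p1, "p1"); p2 <- .as_point3(p2, "p2")
  p3 <- .as_point3(p3, "p3")
  n <- .cross3(p2 - p1, p3 - p1)
  if (.norm3(n) / 2 <= .tmj_tol$area) {
    stop("degenerate geometry: the three points are collinear or coincident",
         call. = FALSE)
  }
  plane(n, p1)
}

#' Plane through two points, perpendicular to a base plane
#'
#' Contains the line a-b and is perpendicular to `base`; the normal is
#' `normalize((b - a) x base$normal)`.
#'
#' @param base A [plane()] the result must be perpendicular to.
#' @param a,b Distinct points the result passes through; the direction `b - a`
#'   must not be parallel to `base$normal`.
#' @return A [plane()].
#' @export
plane_perpendicular_through_line <- function(base, a, b) {
  stopifnot(inherits(base, "tmj_plane"))
  a <- .as_point3(a, "a"); b <- .as_point3(b, "b")
  d <- b - a
  nd <- .norm3(d)
  if (nd < .tmj_tol$geom) {
    stop("degenerate geometry: a and b coincide", call. = FALSE)
  }
  n <- .cross3(d, base$normal)
  if (.norm3(n) < .tmj_tol$geom * nd) {
    stop("degenerate geometry: line a-b is parallel to the base plane normal",
         call. = FALSE)
  }
  plane(n, a)
}

#' Plane through a point, perpendicular to two planes
#'
#' The normal is `normalize(p1$normal x p2$normal)`.
#'
#' @param p1,p2 Planes with non-parallel normals.
#' @param through Point (mm) the result passes through.
#' @return A [plane()].
#' @export
plane_perpendicular_to_two <- function(p1, p2, through) {
  stopifnot(inherits(p1, "tmj_plane"), inherits(p2, "tmj_plane"))
  n <- .cross3(p1$normal, p2$normal)
  if (.norm3(n) < .tmj_tol$geom) {
    stop("degenerate geometry: the two plane normals are parallel",
         call. = FALSE)
  }
  plane(n, .as_point3(through, "through"))
}

#' Plane parallel to a base plane through a point
#'
#' @param base A [plane()]; its normal is reused unchanged.
#' @param p Point (mm) the result passes through.
#' @return A [plane()].
#' @export
plane_parallel_through_point <- function(base, p) {
  stopifnot(inherits(base, "tmj_plane"))
  plane(base$normal, p)
}

#' Signed distance from a plane to points
#'
#' `dot(normal, p - plane$point)`: positive on the side the stored normal
#' points to.
#'
#' @param plane A [plane()].
#' @param p A numeric xyz or an n x 3 matrix of points (mm).
#' @return Numeric vector of signed distances (mm).
#' @export
signed_distance <- function(plane, p) {
  stopifnot(inherits(plane, "tmj_plane"))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    drop((p - matrix(plane$point, nrow(p), 3, byrow = TRUE)) %*% plane$normal)
  } else {
    sum(plane$normal * (.as_point3(p) - plane$point))
  }
}

# Apply a rigid transform to a plane (normal rotates, point maps).
transform_plane <- function(tf, pl) {
  stopifnot(inherits(tf, "tmj_rigid"), inherits(pl, "tmj_plane"))
  plane(drop(tf$rotation %*% pl$normal), apply_rigid(tf, pl$point))
}
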