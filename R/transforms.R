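# Rigid (rotation + translation) transforms and landmark-based registration.

#' Rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric xyz (mm).
#' @return Object of class `tmj_rigid` with fields `rotation`, `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  tol <- .tmj_tol$geom * 1e3   # allow accumulated round-off from products
  if (max(abs(crossprod(rotation) - diag(3))) > tol ||
      abs(det(rotation) - 1) > tol) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation,
                 translation = .as_point3(translation, "translation")),
            class = "tmj_rigid")
}

#' @export
print.tmj_rigid <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid transform> rotation %.4f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix about an axis
#'
#' @param axis Numeric xyz axis (normalised internally).
#' @param angle_deg Rotation angle, degrees, right-handed about `axis`.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- .unit3(.as_point3(axis, "axis"), "rotation axis")
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees in `[0, 180]`.
#' @export
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param tf A [rigid_transform()].
#' @param p A numeric xyz or an n x 3 matrix of points.
#' @return Transformed points, same shape as `p`.
#' @export
apply_rigid <- function(tf, p) {
  stopifnot(inherits(tf, "tmj_rigid"))
  if (is.matrix(p)) {
    p %*% t(tf$rotation) +
      matrix(tf$translation, nrow(p), 3, byrow = TRUE)
  } else {
    drop(tf$rotation %*% .as_point3(p)) + tf$translation
  }
}

#' Compose rigid transforms
#'
#' `compose_rigid(a, b)` applies `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @return The composed [rigid_transform()].
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_rigid <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, drop(-Rt %*% tf$translation))
}

# Kabsch: least-squares rotation + translation (no scaling, no reflection)
# for paired point sets given as n x 3 matrices.
.kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cd - drop(R %*% cs))
}

#' Least-squares rigid transform from three point correspondences
#'
#' The 3-point superimposition used to align serial scans on the unchanged
#' cranial base: a Kabsch least-squares fit (rotation + translation, no
#' scaling or reflection) of the source landmark triangle onto the target
#' triangle. The two triangles need not be congruent.
#'
#' @param src,dst 3 x 3 matrices (one landmark per row, xyz columns, mm).
#' @return A [rigid_transform()] minimising `sum |R s_i + t - d_i|^2`.
#' @export
rigid_from_three_correspondences <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(all(dim(src) == c(3L, 3L)), all(dim(dst) == c(3L, 3L)))
  for (m in list(src, dst)) {
    a <- .norm3(.cross3(m[2, ] - m[1, ], m[3, ] - m[1, ])) / 2
    if (a <= .tmj_tol$area) {
      stop("degenerate geometry: landmark triple is collinear", call. = FALSE)
    }
  }
  .kabsch(src, dst)
}
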