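#' Rigid transform (rotation + translation)
#'
#' Constructs a proper rigid-body transform in 3D, the building block of the
#' articulated spine model: intervertebral transforms, global per-vertebra
#' transforms and the cross-modality bone transforms are all of this type.
#' Rotations are stored as 3x3 matrices (not Euler angles) to avoid gimbal
#' ambiguity; see [euler_angles()] for reporting.
#'
#' @param rotation 3x3 proper orthonormal matrix (R'R = I, det = +1).
#' @param translation length-3 numeric vector, mm.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (!is_rotation_matrix(rotation))
    stop("rotation must be proper orthonormal (R'R = I, det(R) = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

is_rotation_matrix <- function(R, tol = 1e-8) {
  is.numeric(R) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

assert_rigid <- function(x) {
  if (!inherits(x, "rigid_transform")) stop("expected a rigid_transform")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_rigid(t2, t1)` applies `t1` first, then `t2` — the right-to-left
#' convention of transform chains, so composing a chain of intervertebral
#' transforms from the root vertebra upward reproduces the global transform.
#'
#' @param t2,t1 `rigid_transform` objects; `t1` is applied first.
#' @return A `rigid_transform`.
#' @export
compose_rigid <- function(t2, t1) {
  assert_rigid(t2); assert_rigid(t1)
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  assert_rigid(tf)
  Rt <- t(tf$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% tf$translation))
}

#' Apply a rigid transform to points
#'
#' @param tf A `rigid_transform`.
#' @param points Either a length-3 vector or an n x 3 matrix of points (mm).
#' @return Points of the same shape, transformed.
#' @export
apply_rigid <- function(tf, points) {
  assert_rigid(tf)
  if (is.null(dim(points))) {
    as.numeric(tf$rotation %*% points) + tf$translation
  } else {
    sweep(points %*% t(tf$rotation), 2L, tf$translation, "+")
  }
}

#' Convert a rigid transform to/from a 4x4 homogeneous matrix
#' @param tf A `rigid_transform`.
#' @return `rigid_to_matrix`: a 4x4 matrix; `rigid_from_matrix`: a
#'   `rigid_transform`.
#' @export
rigid_to_matrix <- function(tf) {
  assert_rigid(tf)
  m <- diag(4)
  m[1:3, 1:3] <- tf$rotation
  m[1:3, 4] <- tf$translation
  m
}

#' @rdname rigid_to_matrix
#' @param m A 4x4 homogeneous matrix with a proper orthonormal upper-left block.
#' @export
rigid_from_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) stop("expected a 4x4 matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Euler angles (XYZ intrinsic, degrees) of a rotation, for reporting
#' @param tf A `rigid_transform` or 3x3 rotation matrix.
#' @return Named numeric vector `c(rx, ry, rz)` in degrees.
#' @export
euler_angles <- function(tf) {
  R <- if (inherits(tf, "rigid_transform")) tf$rotation else as.matrix(tf)
  sy <- sqrt(R[1, 1]^2 + R[2, 1]^2)
  if (sy > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3]); ry <- atan2(-R[3, 1], sy)
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2]); ry <- atan2(-R[3, 1], sy); rz <- 0
  }
  c(rx = rx, ry = ry, rz = rz) * 180 / pi
}

#' Small rotation from axis angles
#'
#' Rotation about the x, y then z axes (applied in that order), in degrees.
#' Used by the phantom to draw per-joint prone perturbations.
#' @param rx,ry,rz Rotation angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_xyz <- function(rx = 0, ry = 0, rz = 0) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- euler_angles(x)
  cat(sprintf("rigid_transform: rot (deg) [%.2f, %.2f, %.2f], trans (mm) [%.2f, %.2f, %.2f]\n",
              ang[1], ang[2], ang[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}
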