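# Quaternion and rotation helpers.
#
# Convention: scalar-first unit quaternions (w, x, y, z) with the Hamilton
# product. An *attitude* quaternion q rotates sensor/body-frame vectors into
# the ground frame: v_ground = q (0, v_body) q*.

#' Hamilton product of two quaternions
#'
#' @param a,b Numeric length-4 vectors, scalar-first.
#' @return Numeric length-4 vector `a %qm% b`.
#' @keywords internal
quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @keywords internal
quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("cannot normalize a near-zero quaternion")
  q / n
}

#' Rotate a 3-vector by a unit quaternion (body -> ground for attitudes)
#' @keywords internal
quat_rotate <- function(q, v) {
  out <- quat_mult(quat_mult(q, c(0, v)), quat_conj(q))
  out[2:4]
}

#' Quaternion for a rotation of `angle` radians about `axis`
#' @keywords internal
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix R with v_ground = R v_body for attitude quaternion q
#' @keywords internal
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Attitude quaternion from a proper rotation matrix (Shepperd's method)
#' @keywords internal
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' Spherical linear interpolation between hemisphere-aligned quaternions
#'
#' @param q0,q1 Unit quaternions. `q1` is sign-flipped if the pair straddles
#'   hemispheres, so the short arc is always taken.
#' @param t Interpolation fraction in `[0, 1]` (vectorised).
#' @return Matrix `length(t) x 4` of unit quaternions.
#' @keywords internal
quat_slerp <- function(q0, q1, t) {
  if (sum(q0 * q1) < 0) q1 <- -q1
  d <- max(-1, min(1, sum(q0 * q1)))
  theta <- acos(d)
  out <- matrix(NA_real_, length(t), 4)
  if (theta < 1e-10) {
    for (i in seq_along(t)) {
      out[i, ] <- quat_normalize((1 - t[i]) * q0 + t[i] * q1)
    }
  } else {
    s <- sin(theta)
    for (i in seq_along(t)) {
      out[i, ] <- (sin((1 - t[i]) * theta) * q0 + sin(t[i] * theta) * q1) / s
    }
  }
  out
}

#' Rotation matrix about a principal or arbitrary axis
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  quat_to_matrix(quat_from_axis_angle(axis, angle))
}

#' Euler XYZ (intrinsic) rotation matrix, angles in radians
#' @keywords internal
euler_xyz_to_matrix <- function(rx, ry, rz) {
  rotation_about_axis(c(1, 0, 0), rx) %*%
    rotation_about_axis(c(0, 1, 0), ry) %*%
    rotation_about_axis(c(0, 0, 1), rz)
}

#' Intrinsic XYZ Euler angles (radians) from a rotation matrix
#' @keywords internal
matrix_to_euler_xyz <- function(R) {
  # R = Rx(rx) Ry(ry) Rz(rz)
  ry <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  } else {
    rx <- atan2(R[3, 2], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz)
}

#' Uniformly random rotation (Shoemake's subgroup algorithm)
#' @keywords internal
random_rotation <- function(rng_unif = stats::runif) {
  u <- rng_unif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_matrix(quat_normalize(q))
}

#' Geodesic angle (radians) between two rotations
#' @keywords internal
rotation_angle_between <- function(R1, R2) {
  R <- t(R1) %*% R2
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
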