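#' Quaternion and rigid-body frame utilities
#'
#' Quaternions are stored as length-4 numeric vectors `(w, x, y, z)` and
#' represent rotations of world-frame vectors; angular velocities are world
#' frame throughout the package. These helpers are the single source of truth
#' for orientation conventions: every other module (elasticity, integrator,
#' collision, the compiled engine) uses the same storage order and the same
#' left-multiplied exponential-map update.
#'
#' @name quaternions
#' @keywords internal
NULL

#' @rdname quaternions
#' @param q,q1,q2 quaternions as numeric `(w, x, y, z)`.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n == 0) stop("cannot normalize a zero quaternion", call. = FALSE)
  q / n
}

#' @rdname quaternions
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; x1 <- q1[2]; y1 <- q1[3]; z1 <- q1[4]
  w2 <- q2[1]; x2 <- q2[2]; y2 <- q2[3]; z2 <- q2[4]
  c(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' @rdname quaternions
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 orthonormal rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quaternions
#' @param v 3-vector to rotate.
#' @export
quat_rotate <- function(q, v) {
  # R(q) v without forming the matrix
  qv <- c(q[2], q[3], q[4])
  t <- 2 * cross3(qv, v)
  v + q[1] * t + cross3(qv, t)
}

#' Quaternion from an axis-angle rotation
#'
#' @param axis rotation axis (need not be unit length).
#' @param angle rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Cross product of two 3-vectors
#' @param a,b 3-vectors.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' `skew3(r) %*% v` equals `cross3(r, v)`; used for the lever-arm blocks of
#' constraint Jacobians.
#' @param r 3-vector.
#' @export
skew3 <- function(r) {
  matrix(c(0, -r[3], r[2],
           r[3], 0, -r[1],
           -r[2], r[1], 0), nrow = 3, byrow = TRUE)
}

#' Exponential-map quaternion update
#'
#' Advances an orientation by a world-frame angular velocity over one
#' timestep: `q' = exp(omega * dt / 2) * q`, where `exp` is the quaternion
#' exponential of a pure vector. A series branch handles `|omega| * dt -> 0`
#' so the map is globally smooth; the result is renormalized to guard against
#' round-off accumulation.
#'
#' @param q unit quaternion.
#' @param omega world-frame angular velocity (rad per time unit).
#' @param dt timestep.
#' @return updated unit quaternion.
#' @export
exp_map_update <- function(q, omega, dt) {
  a <- omega * dt / 2
  th <- sqrt(sum(a^2))
  if (th < 1e-8) {
    # sin(th)/th = 1 - th^2/6 + O(th^4)
    s <- 1 - th * th / 6
    dq <- c(1 - th * th / 2, s * a)
  } else {
    dq <- c(cos(th), sin(th) / th * a)
  }
  quat_normalize(quat_multiply(dq, q))
}

#' Orthonormal body triad of a cylinder
#'
#' Returns the principal-axis triad `(t, u, v)` of a body with orientation
#' `q`: `t` is the cylinder tangent (the body z axis rotated to the world),
#' `u` a normal to it and `v = t x u`. Columns of the returned matrix are
#' `t`, `u`, `v` in that order.
#'
#' @param q unit quaternion (checked to 1e-6).
#' @return 3x3 matrix with columns `t`, `u`, `t x u`.
#' @export
body_frame <- function(q) {
  n <- sqrt(sum(q * q))
  if (abs(n - 1) > 1e-6) {
    stop("body_frame(): quaternion is not normalized (|q| = ", format(n), ")",
         call. = FALSE)
  }
  R <- quat_to_matrix(q / n)
  out <- cbind(t = R[, 3], u = R[, 1], v = R[, 2])
  colnames(out) <- c("t", "u", "v")
  out
}

#' Principal moments of inertia of a solid cylinder
#'
#' The chain cylinders are treated as solid cylinders for inertia (and as
#' capsules only for collision geometry). Moments are returned about the
#' centre of mass as `(I_perp, I_perp, I_axis)` with the symmetry axis third,
#' matching the tangent-last column order of [body_frame()].
#'
#' @param mass cylinder mass.
#' @param radius cylinder radius.
#' @param length cylinder length.
#' @return numeric length-3: two equal transverse moments, then the axial one.
#' @export
capsule_inertia <- function(mass, radius, length) {
  if (any(c(mass, radius, length) <= 0)) {
    stop("capsule_inertia(): mass, radius and length must be positive",
         call. = FALSE)
  }
  if (radius >= length / 2) {
    message("capsule_inertia(): radius >= length/2; body is near-spherical")
  }
  i_axis <- mass * radius^2 / 2
  i_perp <- mass * (length^2 / 12 + radius^2 / 4)
  c(i_perp, i_perp, i_axis)
}

# wrap an angle to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}
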