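#' Rigid-body chain state
#'
#' A `chain_state` collects the instantaneous mechanical state of all rigid
#' bodies: centre-of-mass positions, unit quaternions, linear and (world
#' frame) angular velocities, masses, body-frame principal inertia moments
#' and shape tags. Everything is in reduced units (see [make_unit_system()]).
#'
#' @param pos N x 3 matrix of centre-of-mass positions.
#' @param quat N x 4 matrix of unit quaternions `(w, x, y, z)`.
#' @param vel,angvel N x 3 matrices of linear / world-frame angular
#'   velocities (default zero).
#' @param mass length-N masses.
#' @param inertia N x 3 body-frame principal moments (tangent axis third).
#' @param shape data frame with columns `type` ("capsule", "sphere"),
#'   `radius`, `length`.
#' @param time simulation time in tau units.
#' @return an object of class `chain_state`.
#' @export
chain_state <- function(pos, quat, vel = NULL, angvel = NULL, mass, inertia,
                        shape, time = 0) {
  pos <- as.matrix(pos); quat <- as.matrix(quat)
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(angvel)) angvel <- matrix(0, n, 3)
  stopifnot(nrow(quat) == n, ncol(quat) == 4, length(mass) == n,
            nrow(inertia) == n, nrow(shape) == n)
  nq <- sqrt(rowSums(quat^2))
  if (any(abs(nq - 1) > 1e-6)) stop("chain_state(): non-unit quaternion")
  quat <- quat / nq
  if (any(mass <= 0) || any(inertia <= 0)) {
    stop("chain_state(): masses and inertia moments must be positive")
  }
  structure(list(pos = pos, quat = quat, vel = as.matrix(vel),
                 angvel = as.matrix(angvel), mass = as.numeric(mass),
                 inertia = as.matrix(inertia), shape = shape, time = time),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("<chain_state> %d bodies, t = %.4g tau\n", n_bodies(x), x$time))
  cat(sprintf("  kinetic energy = %.4g kBT\n", kinetic_energy(x)))
  invisible(x)
}

#' @rdname chain_state
#' @param state a `chain_state`.
#' @export
n_bodies <- function(state) nrow(state$pos)

#' Generalized velocity vector
#'
#' Stacks per-body `(v_i, omega_i)` into the length-6N column used by the
#' constraint solver.
#' @param state a [chain_state()].
#' @export
generalized_velocity <- function(state) {
  as.numeric(t(cbind(state$vel, state$angvel)))
}

#' Replace velocities from a generalized velocity vector
#' @param state a [chain_state()].
#' @param u length-6N generalized velocity.
#' @export
set_generalized_velocity <- function(state, u) {
  m <- matrix(u, ncol = 6, byrow = TRUE)
  state$vel <- m[, 1:3, drop = FALSE]
  state$angvel <- m[, 4:6, drop = FALSE]
  state
}

#' World-frame inertia tensor of one body
#' @param state a [chain_state()].
#' @param i body index.
#' @export
world_inertia <- function(state, i) {
  R <- quat_to_matrix(state$quat[i, ])
  # principal order (perp, perp, axis) matches body axes (x, y, z = tangent)
  R %*% diag(state$inertia[i, ]) %*% t(R)
}

#' Generalized mass matrix
#'
#' Block diagonal of `(M_i, I_i)` in world frame; symmetric positive
#' definite for any valid state. Dense; intended for reference computations
#' and tests (the compiled engine applies `W^{-1}` blockwise).
#' @param state a [chain_state()].
#' @export
generalized_mass <- function(state) {
  n <- n_bodies(state)
  W <- matrix(0, 6 * n, 6 * n)
  for (i in seq_len(n)) {
    o <- 6 * (i - 1)
    W[o + 1:3, o + 1:3] <- diag(rep(state$mass[i], 3))
    W[o + 4:6, o + 4:6] <- world_inertia(state, i)
  }
  W
}

#' Kinetic energy of the chain
#'
#' `E = 1/2 u^T W u`, i.e. translational plus rotational kinetic energy.
#' @param state a [chain_state()].
#' @export
kinetic_energy <- function(state) {
  e <- 0.5 * sum(state$mass * rowSums(state$vel^2))
  for (i in seq_len(n_bodies(state))) {
    Iw <- world_inertia(state, i)
    w <- state$angvel[i, ]
    e <- e + 0.5 * sum(w * (Iw %*% w))
  }
  e
}

#' Tidy view of a chain state
#'
#' One row per body with positions, quaternions, velocities and shape, for
#' piping into dplyr/ggplot2.
#' @param x a [chain_state()].
#' @param ... unused.
#' @export
as_tibble.chain_state <- function(x, ...) {
  tibble::tibble(
    body = seq_len(n_bodies(x)),
    type = x$shape$type,
    x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
    qw = x$quat[, 1], qx = x$quat[, 2], qy = x$quat[, 3], qz = x$quat[, 4],
    vx = x$vel[, 1], vy = x$vel[, 2], vz = x$vel[, 3],
    wx = x$angvel[, 1], wy = x$angvel[, 2], wz = x$angvel[, 3],
    mass = x$mass, radius = x$shape$radius, length = x$shape$length
  )
}

#' Ball-and-socket joints of a chain
#'
#' Joints are stored as a tibble, one row per joint: `type` ("ball" or
#' "weld"), 1-based body indices `a` and `b` (`a = 0L` denotes the static
#' world/anchor), body-frame attachment points, and for welds the reference
#' relative quaternion that the orientation rows drive toward.
#'
#' @param type character vector, "ball" or "weld".
#' @param a,b integer body indices (0 = world).
#' @param anchor_a,anchor_b k x 3 body-frame attachment points (for `a = 0`,
#'   `anchor_a` is the world-frame anchor point).
#' @param qref optional k x 4 reference relative quaternions (welds).
#' @export
joint_table <- function(type, a, b, anchor_a, anchor_b, qref = NULL) {
  k <- length(type)
  anchor_a <- matrix(anchor_a, k, 3)
  anchor_b <- matrix(anchor_b, k, 3)
  if (is.null(qref)) qref <- matrix(rep(c(1, 0, 0, 0), each = k), k, 4)
  tibble::tibble(
    type = type, a = as.integer(a), b = as.integer(b),
    ax = anchor_a[, 1], ay = anchor_a[, 2], az = anchor_a[, 3],
    bx = anchor_b[, 1], by = anchor_b[, 2], bz = anchor_b[, 3],
    qw = qref[, 1], qx = qref[, 2], qy = qref[, 3], qz = qref[, 4]
  )
}

# number of constraint rows contributed by each joint row
joint_rows <- function(joints) ifelse(joints$type == "weld", 6L, 3L)

# world position of a joint anchor on one side
anchor_world <- function(state, body, local) {
  if (body == 0L) return(local)
  state$pos[body, ] + quat_rotate(state$quat[body, ], local)
}
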