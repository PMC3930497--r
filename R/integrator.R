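#' One semi-implicit Euler step (reference implementation)
#'
#' Advances a chain state by one timestep: velocities first
#' (`u' = u + dt W^{-1} (F_ext + J^T lambda)` with `lambda` from the
#' constraint solve), then positions from the *new* velocities, then
#' orientations through the exponential map. Quaternions are renormalized
#' every step. This dense R implementation defines the semantics the
#' compiled engine reproduces; it is used directly by the unit tests and for
#' small systems.
#'
#' The gyroscopic torque `-w x (I_world w)` is part of the force assembly
#' (see [assemble_forces()]), not of this update.
#'
#' @param state a [chain_state()].
#' @param F_ext generalized external force (length 6N).
#' @param joints a [joint_table()] (may have zero rows).
#' @param dt timestep.
#' @param solver_params list: `erp`, `cfm`, `sor_omega`, `sor_iter`,
#'   `accept_tol`.
#' @param contacts optional contact list from [detect_contacts()].
#' @param v_target optional per-row target constraint velocities for
#'   kinematic clamp rows appended after the joint rows.
#' @return the updated `chain_state`.
#' @export
step_state <- function(state, F_ext, joints, dt,
                       solver_params = list(erp = 0.8, cfm = 1e-10),
                       contacts = NULL, v_target = NULL) {
  if (any(!is.finite(F_ext))) {
    stop("step_state(): non-finite external force; state dump: t = ",
         state$time, call. = FALSE)
  }
  n <- n_bodies(state)
  u <- generalized_velocity(state)
  W <- generalized_mass(state)
  erp <- solver_params$erp %||% 0.8
  cfm <- solver_params$cfm %||% 1e-10
  has_joints <- nrow(joints) > 0 || length(contacts) > 0
  if (has_joints) {
    C <- evaluate_constraints(state, joints)
    lo <- rep(-Inf, length(C)); hi <- rep(Inf, length(C))
    vt <- rep(0, length(C))
    if (length(contacts)) {
      cr <- contact_rows(contacts, erp, dt)
      C <- c(C, cr$C); lo <- c(lo, cr$lo); hi <- c(hi, cr$hi)
      vt <- c(vt, cr$v_target)
    }
    if (!is.null(v_target)) vt[seq_along(v_target)] <- v_target
    J <- assemble_jacobian(state, joints, contacts)
    sys <- build_system(J, W, F_ext, u, dt, erp, cfm, C,
                        v_target = vt, lo = lo, hi = hi)
    sizes <- if (length(contacts) == 0) joint_rows(joints) else NULL
    sol <- dispatch_solver(sys, has_collisions = length(contacts) > 0,
                           sor_params = list(omega = solver_params$sor_omega %||% 1.3,
                                             n_iter = solver_params$sor_iter %||% 64),
                           accept_tol = solver_params$accept_tol %||% 1e-6,
                           sizes = sizes)
    u_new <- sys$uf + dt * as.numeric(sys$Winv %*% constraint_force(J, sol$lambda))
  } else {
    u_new <- u + dt * as.numeric(solve(W, F_ext))
  }
  state <- set_generalized_velocity(state, u_new)
  state$pos <- state$pos + dt * state$vel
  for (i in seq_len(n)) {
    state$quat[i, ] <- exp_map_update(state$quat[i, ], state$angvel[i, ], dt)
  }
  state$time <- state$time + dt
  state
}

#' Assemble generalized external forces (reference implementation)
#'
#' Sums, for each body, applied forces/torques, the elastic restoring
#' torques of the chain joints and the gyroscopic term `-w x (I_world w)`
#' of the Newton-Euler equations. Thermostat forces are added separately by
#' the caller so their decoupling properties can be tested in isolation.
#'
#' @param state a [chain_state()].
#' @param elastic an [elastic_params()] or `NULL`.
#' @param applied_force,applied_torque optional N x 3 matrices.
#' @param chain_bodies indices of consecutive chain cylinders carrying
#'   elasticity (default: all capsules in order).
#' @return generalized force vector (length 6N).
#' @export
assemble_forces <- function(state, elastic = NULL, applied_force = NULL,
                            applied_torque = NULL, chain_bodies = NULL) {
  n <- n_bodies(state)
  f <- numeric(6 * n)
  for (i in seq_len(n)) {
    o <- 6 * (i - 1)
    if (!is.null(applied_force)) f[o + 1:3] <- f[o + 1:3] + applied_force[i, ]
    if (!is.null(applied_torque)) f[o + 4:6] <- f[o + 4:6] + applied_torque[i, ]
    Iw <- world_inertia(state, i)
    w <- state$angvel[i, ]
    f[o + 4:6] <- f[o + 4:6] - cross3(w, as.numeric(Iw %*% w))
  }
  if (!is.null(elastic)) {
    if (is.null(chain_bodies)) chain_bodies <- which(state$shape$type == "capsule")
    for (k in seq_len(length(chain_bodies) - 1)) {
      i <- chain_bodies[k]; j <- chain_bodies[k + 1]
      tq <- restoring_torque(body_frame(state$quat[i, ]),
                             body_frame(state$quat[j, ]), elastic)
      oi <- 6 * (i - 1); oj <- 6 * (j - 1)
      f[oi + 4:6] <- f[oi + 4:6] + tq$torque_i
      f[oj + 4:6] <- f[oj + 4:6] + tq$torque_i1
    }
  }
  f
}
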