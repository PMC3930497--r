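#' Solver parameter set
#'
#' Velocity-level constraint-solver settings. `erp` is the per-step
#' fractional correction of bearing separations (0.8 by default), `cfm` the
#' constraint-force-mixing softening that keeps the system strictly positive
#' definite, `sor_omega`/`sor_iter` the successive over-relaxation settings
#' used when contacts are present, `accept_tol` the accepted per-step
#' bearing-separation growth (in units of b) above which the step is
#' re-solved with the direct solver, and `max_push` the cap on the contact
#' push-out velocity (b/tau).
#'
#' @param erp error-reduction parameter in `[0, 1]`.
#' @param cfm constraint force mixing (>= 0).
#' @param sor_omega SOR relaxation factor in (0, 2).
#' @param sor_iter SOR sweeps per step.
#' @param accept_tol SOR acceptance threshold.
#' @param force_direct always use the direct solver (debugging).
#' @param contact_erp error reduction used on contact rows (defaults to
#'   `erp`).
#' @param max_push contact push-out velocity cap.
#' @export
solver_params <- function(erp = 0.8, cfm = 1e-10, sor_omega = 1.3,
                          sor_iter = 64, accept_tol = 1e-6,
                          force_direct = FALSE, contact_erp = erp,
                          max_push = 1) {
  if (erp < 0 || erp > 1) stop("solver_params(): erp must be in [0, 1]", call. = FALSE)
  if (cfm < 0) stop("solver_params(): cfm must be >= 0", call. = FALSE)
  if (sor_omega <= 0 || sor_omega >= 2) {
    stop("solver_params(): sor_omega must be in (0, 2)", call. = FALSE)
  }
  list(erp = erp, cfm = cfm, sor_omega = sor_omega, sor_iter = sor_iter,
       accept_tol = accept_tol, force_direct = force_direct,
       contact_erp = contact_erp, max_push = max_push)
}

clamp_mode_int <- function(mode) {
  switch(mode, none = 0L, turn = 1L, torque = 2L,
         stop("unknown clamp mode: ", mode, call. = FALSE))
}

#' Run the compiled simulation engine
#'
#' Advances an assembly by `n_steps` timesteps under the chosen thermostat,
#' protocol drive and solver settings, logging observables every
#' `obs_stride` steps (writhe every `wr_stride`-th logged row) and
#' optionally recording trajectory frames. The returned object carries the
#' updated assembly so successive calls continue the run (ramp, equilibrate,
#' sample).
#'
#' @param assembly an [build_assembly()] (or fixture) object.
#' @param n_steps number of timesteps.
#' @param dt timestep in tau units (0.000592 by default).
#' @param thermostat a [thermostat_params()].
#' @param solver a [solver_params()].
#' @param seed integer seed for the engine RNG stream.
#' @param collisions enable excluded volume.
#' @param force stretching force in reduced units (kBT/b), applied along +z
#'   at the free attachment point (bead centre, or the distal end of the
#'   last cylinder when there is no bead).
#' @param clamp bead clamp: `"none"`, `"turn"` or `"torque"`.
#' @param turns target bead turns for the turn clamp (reached by ramping at
#'   `ramp_rate` from the assembly's current target).
#' @param ramp_rate turn-clamp ramp rate in turns per 1000 steps.
#' @param torque external bead torque (kBT) for the torque clamp.
#' @param obs_stride,traj_stride,wr_stride logging strides (steps, steps,
#'   logged rows); `traj_stride = 0` disables trajectory recording.
#' @return an object of class `rbdna_run`: list with `observables` (tibble),
#'   `trajectory` (or `NULL`), the updated `assembly`, and `diagnostics`.
#' @export
run_simulation <- function(assembly, n_steps, dt = 0.000592,
                           thermostat = thermostat_params("global"),
                           solver = solver_params(), seed = 1,
                           collisions = TRUE, force = 0,
                           clamp = c("none", "turn", "torque"),
                           turns = 0, ramp_rate = 0.05, torque = 0,
                           obs_stride = 100L, traj_stride = 0L,
                           wr_stride = 10L) {
  clamp <- match.arg(clamp)
  # the rescaling thermostat cannot heat a perfectly cold start (its force
  # is proportional to the momentum): seed thermal velocities once
  if (thermostat$mode == "global" && kinetic_energy(assembly$state) == 0) {
    assembly <- thermal_velocities(assembly, kBT = thermostat$kBT,
                                   seed = seed)
  }
  st <- assembly$state
  n <- assembly$n_cylinders
  nb <- n_bodies(st)
  bead <- assembly$bead_index
  has_bead <- !is.na(bead)
  if (clamp != "none" && !has_bead) {
    stop("run_simulation(): bead clamps need an assembly with a bead",
         call. = FALSE)
  }

  joints <- assembly$joints
  jtype <- ifelse(joints$type == "weld", 1L, 0L)

  pull_body <- if (has_bead) bead - 1L else n - 1L
  pull_local <- if (has_bead) c(0, 0, 0) else c(0, 0, 0.5)

  psi_target <- assembly$psi_target
  psi_cap <- 2 * pi * turns
  rate <- 0
  if (clamp == "turn") {
    d_sign <- sign(psi_cap - psi_target)
    rate <- d_sign * 2 * pi * abs(ramp_rate) / (1000 * dt)   # rad per tau
    if (d_sign == 0) rate <- 0
    # sanity: twist added per joint per step must stay well below pi
    if (abs(rate) * dt > pi * (n - 1)) {
      stop("run_simulation(): turn ramp rate too fast for this chain",
           call. = FALSE)
    }
  }

  ndof <- count_dof(assembly, clamp_mode = clamp)

  spec <- list(
    pos = st$pos, quat = st$quat, vel = st$vel, omg = st$angvel,
    mass = st$mass, inertia = st$inertia,
    stype = ifelse(st$shape$type == "capsule", 0L, 1L),
    radius = st$shape$radius, len = st$shape$length,
    jtype = jtype, ja = joints$a - 1L, jb = joints$b - 1L,
    janchor_a = cbind(joints$ax, joints$ay, joints$az),
    janchor_b = cbind(joints$bx, joints$by, joints$bz),
    jqref = cbind(joints$qw, joints$qx, joints$qy, joints$qz),
    epairs = cbind(0:(n - 2L), 1:(n - 1L)),
    g_b = assembly$elastic$g_b, g_t = assembly$elastic$g_t,
    phi_prev = assembly$phi_prev, phi_cum = assembly$phi_cum,
    phi_init = assembly$phi_init,
    clamp_mode = clamp_mode_int(clamp),
    clamp_body = if (has_bead) bead - 1L else -1L,
    psi = assembly$psi, psi_target = psi_target,
    psi_rate = rate, psi_cap = psi_cap,
    torque_z = if (clamp == "torque") torque else 0,
    qbead0 = if (has_bead) st$quat[bead, ] else c(1, 0, 0, 0),
    pull_body = pull_body, pull_local = pull_local,
    pull_force = c(0, 0, force),
    tmode = switch(thermostat$mode, off = 0L, local = 1L, global = 2L),
    gamma = thermostat$gamma, kBT = thermostat$kBT,
    gamma_bg = thermostat$gamma_background %||% 0, ndof = ndof,
    erp = solver$erp, cfm = solver$cfm, sor_omega = solver$sor_omega,
    sor_iter = as.integer(solver$sor_iter), accept_tol = solver$accept_tol,
    force_direct = isTRUE(solver$force_direct),
    contact_erp = solver$contact_erp, max_push = solver$max_push,
    col_enabled = isTRUE(collisions),
    plane_enabled = assembly$anchor != "none",
    first_plane_attached = assembly$anchor != "none",
    excl_window = bonded_exclusion_window(assembly$radius),
    dt = dt, time = st$time, seed = as.double(seed),
    ext_body = n - 1L, ext_local = c(0, 0, 0.5), lk0 = assembly$Lk0
  )

  res <- cpp_run(spec, as.double(n_steps), as.integer(obs_stride),
                 as.integer(max(traj_stride, 1L)), as.integer(wr_stride),
                 traj_stride > 0)

  n_obs <- as.integer(res$n_obs)
  obs <- tibble::as_tibble(res$obs[seq_len(n_obs), , drop = FALSE])
  obs$solver <- c("exact", "sor", "direct")[obs$solver + 1L]
  obs$Wr[is.nan(obs$Wr)] <- NA_real_

  traj <- NULL
  if (traj_stride > 0 && res$n_frames > 0) {
    nf <- as.integer(res$n_frames)
    traj <- list(
      pos = aperm(array(res$traj_pos[seq_len(nf * nb * 3)], c(3, nb, nf)),
                  c(3, 2, 1)),
      quat = aperm(array(res$traj_quat[seq_len(nf * nb * 4)], c(4, nb, nf)),
                   c(3, 2, 1)),
      time = res$traj_time[seq_len(nf)],
      n_cylinders = n
    )
  }

  st$pos <- res$pos; st$quat <- res$quat
  st$vel <- res$vel; st$angvel <- res$omg
  st$time <- res$time
  assembly$state <- st
  assembly$phi_prev <- as.numeric(res$phi_prev)
  assembly$phi_cum <- as.numeric(res$phi_cum)
  assembly$phi_init <- TRUE
  assembly$psi <- res$psi
  assembly$psi_target <- res$psi_target

  structure(list(observables = obs, trajectory = traj, assembly = assembly,
                 diagnostics = res$diag,
                 params = list(dt = dt, thermostat = thermostat,
                               solver = solver, seed = seed, force = force,
                               clamp = clamp, turns = turns, torque = torque,
                               n_steps = n_steps, ndof = ndof)),
            class = "rbdna_run")
}

#' @export
print.rbdna_run <- function(x, ...) {
  o <- x$observables
  cat(sprintf("<rbdna_run> %g steps, %d observation rows, clamp = %s\n",
              x$params$n_steps, nrow(o), x$params$clamp))
  cat(sprintf("  final: E_kin = %.3g kBT, ext = %.3g b, max|C| = %.2g b\n",
              o$E_kin[nrow(o)], o$ext[nrow(o)], x$diagnostics$max_C))
  invisible(x)
}

#' Tangent vectors of the chain from a recorded trajectory
#'
#' Returns an `n_frames x n_cylinders x 3` array of unit tangents computed
#' from the stored quaternions.
#'
#' @param trajectory the `trajectory` element of an [run_simulation()]
#'   result.
#' @export
trajectory_tangents <- function(trajectory) {
  q <- trajectory$quat
  nf <- dim(q)[1]; n <- trajectory$n_cylinders
  tg <- array(0, c(nf, n, 3))
  w <- matrix(q[, seq_len(n), 1], nf, n)
  x <- matrix(q[, seq_len(n), 2], nf, n)
  y <- matrix(q[, seq_len(n), 3], nf, n)
  z <- matrix(q[, seq_len(n), 4], nf, n)
  tg[, , 1] <- 2 * (x * z + w * y)
  tg[, , 2] <- 2 * (y * z - w * x)
  tg[, , 3] <- 1 - 2 * (x^2 + y^2)
  tg
}
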