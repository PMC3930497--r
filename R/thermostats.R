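#' Thermostat parameters
#'
#' Both thermostats share a single coupling frequency `gamma` (reduced
#' 1/tau units) across all translational and rotational degrees of freedom.
#' Under the local (Langevin) thermostat the friction on each body is
#' `-gamma M v` and `-gamma I w` with matched Gaussian noise satisfying the
#' fluctuation-dissipation theorem; the corresponding kinetic-energy
#' autocorrelation time is `1/(2 gamma)`. The global thermostat is a
#' stochastic velocity-rescaling scheme whose correction force is exactly
#' parallel to the generalized momentum `P = W u` and therefore leaves the
#' constraint equations untouched.
#'
#' A caveat on ergodicity: the global thermostat only rescales the
#' generalized momentum, so it relies on the dynamics to mix energy between
#' modes. For a chain *without* twist rigidity (`g_t = 0`, the
#' freely-jointed limit) the axial spin of each symmetric cylinder is an
#' exact integral of the motion -- joint forces exert no axial torque -- and
#' those modes never thermalize, freezing a random share of kinetic energy
#' and biasing the effective temperature of the remaining modes. Use the
#' local thermostat for such chains; with DNA-like `g_t > 0` the twist
#' coupling restores ergodicity.
#'
#' Because the exact solver conserves total linear and angular momentum of
#' a free chain to machine precision, a *pure* rescaling thermostat slowly
#' drains those exactly (or nearly) conserved modes -- the log of the
#' rescaling factor has a negative drift `-2(1-c)/n_dof` per step -- and
#' the remaining modes compensate by running warm. The engine therefore
#' couples a weak local Langevin background (`gamma_background`, default
#' `gamma/100`) alongside the global rescaling: both thermostats target the
#' same canonical measure, so the combination is exact, the background
#' re-thermalizes conserved and quasi-conserved collective modes on a
#' ~`1/(2 gamma_background)` timescale, and the sampling acceleration of
#' the global scheme is preserved. Set `gamma_background = 0` for the pure
#' rescaling scheme.
#'
#' @param mode `"global"`, `"local"` or `"off"`.
#' @param gamma coupling frequency (> 0 unless off); default 10.
#' @param kBT thermal energy in reduced units (default 1).
#' @param gamma_background weak local coupling used by the engine in
#'   global mode (see Details).
#' @export
thermostat_params <- function(mode = c("global", "local", "off"),
                              gamma = 10, kBT = 1,
                              gamma_background = gamma / 100) {
  mode <- match.arg(mode)
  if (mode != "off" && gamma <= 0) {
    stop("thermostat_params(): gamma must be positive", call. = FALSE)
  }
  if (gamma_background < 0) {
    stop("thermostat_params(): gamma_background must be >= 0", call. = FALSE)
  }
  structure(list(mode = mode, gamma = gamma, kBT = kBT,
                 gamma_background = if (mode == "global") gamma_background else 0),
            class = "thermostat_params")
}

#' Local Langevin thermostat force
#'
#' Per body: friction `-gamma m v` (linear) and `-gamma I_world w`
#' (angular), plus Gaussian noise of per-component variance
#' `2 gamma kBT m / dt` (resp. `2 gamma kBT I_k / dt` along each principal
#' axis, generated in the body frame and rotated to the world). The
#' friction/noise pairing is the discrete fluctuation-dissipation relation
#' for an Euler step of length `dt`.
#'
#' Noise is drawn from R's RNG (`rnorm`), in body order, linear before
#' angular; the compiled engine uses its own deterministic stream with the
#' same convention.
#'
#' @param state a [chain_state()].
#' @param params a [thermostat_params()] with `mode = "local"`.
#' @param dt timestep.
#' @return generalized force (length 6N).
#' @export
local_langevin_force <- function(state, params, dt) {
  stopifnot(params$mode == "local")
  n <- n_bodies(state)
  f <- numeric(6 * n)
  g <- params$gamma; kBT <- params$kBT
  for (i in seq_len(n)) {
    o <- 6 * (i - 1)
    m <- state$mass[i]
    R <- quat_to_matrix(state$quat[i, ])
    Iw <- R %*% diag(state$inertia[i, ]) %*% t(R)
    f[o + 1:3] <- -g * m * state$vel[i, ] +
      sqrt(2 * g * kBT * m / dt) * stats::rnorm(3)
    xi <- sqrt(2 * g * kBT * state$inertia[i, ] / dt) * stats::rnorm(3)
    f[o + 4:6] <- -g * as.numeric(Iw %*% state$angvel[i, ]) +
      as.numeric(R %*% xi)
  }
  f
}

#' Global (stochastic velocity rescaling) thermostat force
#'
#' Draws the exact one-step velocity-rescaling factor `alpha` for the
#' canonical kinetic-energy target `n_dof kBT / 2` with kinetic-energy
#' relaxation time `1/(2 gamma)` (matching the local thermostat at equal
#' `gamma`), and returns the generalized force `((alpha - 1)/dt) W u` that
#' realizes the rescaling under the Euler velocity update. The force is a
#' scalar multiple of the generalized momentum `P = W u`, so it is exactly
#' parallel to `P` and its contribution to the constraint right-hand side,
#' `J W^{-1} F = ((alpha-1)/dt) J u`, vanishes whenever the constraints are
#' satisfied. The stationary kinetic-energy law is the Gamma density with
#' shape `n_dof/2` and scale `kBT`.
#'
#' A cold start (`u = 0`) returns zero force for that step.
#'
#' @param state a [chain_state()].
#' @param params a [thermostat_params()] with `mode = "global"`.
#' @param n_dof number of degrees of freedom from [count_dof()].
#' @param dt timestep.
#' @return list with the generalized `force` and the drawn `alpha`.
#' @export
global_thermostat_force <- function(state, params, n_dof, dt) {
  stopifnot(params$mode == "global")
  K <- kinetic_energy(state)
  n <- n_bodies(state)
  if (K <= 0) return(list(force = numeric(6 * n), alpha = 1))
  kBT <- params$kBT
  cc <- exp(-2 * params$gamma * dt)
  r1 <- stats::rnorm(1)
  s <- if (n_dof > 1) stats::rchisq(1, df = n_dof - 1) else 0
  Kbar <- n_dof * kBT / 2
  a2 <- cc + (1 - cc) * (r1^2 + s) * kBT / (2 * K) +
    2 * r1 * sqrt(cc * (1 - cc) * kBT / (2 * K))
  alpha <- sign(r1 + sqrt(2 * cc * K / ((1 - cc) * kBT))) * sqrt(a2)
  P <- as.numeric(generalized_mass(state) %*% generalized_velocity(state))
  list(force = (alpha - 1) / dt * P, alpha = alpha, K = K, Kbar = Kbar)
}

#' Constraint decoupling residual of a thermostat force
#'
#' Measures `|| J W^{-1} F ||_inf`: for the global thermostat force this is
#' a scalar multiple of `J u` and must vanish whenever the constraints hold,
#' whereas a local-thermostat force generically disturbs the constraint
#' equations.
#'
#' @param state a [chain_state()].
#' @param force generalized force.
#' @param joints a [joint_table()].
#' @export
thermostat_constraint_decoupling_check <- function(state, force, joints) {
  J <- assemble_jacobian(state, joints)
  Winv <- solve(generalized_mass(state))
  max(abs(J %*% Winv %*% force))
}
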