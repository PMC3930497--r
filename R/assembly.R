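#' Effective DNA radius from the salt concentration
#'
#' DNA-DNA electrostatic repulsion is folded into the hard-core geometry by
#' inflating the crystallographic radius with the Debye screening length of
#' the monovalent buffer, `lambda_D = 0.304 / sqrt(c)` nm with `c` in mol/L.
#' The effective radius decreases monotonically with salt.
#'
#' @param salt_mM monovalent salt concentration in mmol/L.
#' @param r_crystallographic_nm bare double-helix radius (1 nm).
#' @return effective radius in nm.
#' @examples
#' effective_radius(100)  # ~1.96 nm (high salt)
#' effective_radius(10)   # ~4.04 nm (low salt)
#' @export
effective_radius <- function(salt_mM, r_crystallographic_nm = 1) {
  if (any(salt_mM <= 0)) stop("effective_radius(): salt_mM must be positive",
                              call. = FALSE)
  debye_nm <- 0.304 / sqrt(salt_mM / 1000)
  r_crystallographic_nm + debye_nm
}

#' Build a magnetic-tweezers assembly
#'
#' Constructs the chain of `n` capsules in reduced units (b = 1), optionally
#' anchored to the z = 0 plane and capped by a magnetic bead welded to the
#' last cylinder. The default build is a straight vertical chain with all
#' joint bearings exactly coincident (C = 0) and zero velocities, which is a
#' static equilibrium of the elastic energy. With `end_tangency = TRUE` the
#' first and last cylinders are instead laid tangent to their attachment
#' surfaces (the grafting geometry of a real tweezers experiment), which
#' starts the chain with two right-angle bends that relax thermally.
#'
#' @param n_cylinders number of chain cylinders (>= 2). 300 corresponds to a
#'   3 kb molecule at 10 bp per cylinder.
#' @param radius capsule radius in reduced units; default from `salt_mM`
#'   through [effective_radius()].
#' @param salt_mM monovalent salt concentration used for the default radius.
#' @param units a [make_unit_system()].
#' @param l_p_nm,l_t_nm bending / twisting persistence lengths in nm.
#' @param g_b,g_t explicit rigidity overrides (kBT), bypassing calibration.
#' @param anchor `"weld"` (torsionally clamped, default), `"ball"` or
#'   `"none"`.
#' @param bead attach a magnetic bead sphere to the last cylinder.
#' @param bead_radius_nm,bead_mass bead radius (nm) and mass (cylinder
#'   masses). The bead is large enough to block end looping; its mass is
#'   kept small since equilibrium observables do not depend on it.
#' @param end_tangency lay the terminal cylinders tangent to their
#'   attachment surfaces.
#' @return an object of class `assembly`.
#' @export
build_assembly <- function(n_cylinders = 300, radius = NULL, salt_mM = 100,
                           units = make_unit_system(),
                           l_p_nm = 50, l_t_nm = 95, g_b = NULL, g_t = NULL,
                           anchor = c("weld", "ball", "none"), bead = TRUE,
                           bead_radius_nm = 50, bead_mass = 10,
                           end_tangency = FALSE) {
  anchor <- match.arg(anchor)
  n <- as.integer(n_cylinders)
  if (n < 2) stop("build_assembly(): need at least 2 cylinders", call. = FALSE)
  if (is.null(radius)) radius <- effective_radius(salt_mM) / units$b_nm
  if (radius >= 1) {
    warning("effective radius >= cylinder length; capsules are wider than long")
  }
  el <- elastic_params(l_p = l_p_nm, l_t = l_t_nm, b = units$b_nm,
                       g_b = g_b, g_t = g_t)

  nb <- n + if (bead) 1L else 0L
  pos <- matrix(0, nb, 3)
  quat <- matrix(rep(c(1, 0, 0, 0), each = nb), nb, 4)
  q_xplus <- quat_from_axis_angle(c(0, 1, 0), pi / 2)  # tangent +z -> +x
  z0 <- if (end_tangency) radius else 0   # tangent first segment rests on plane
  first_horizontal <- end_tangency && anchor != "none"
  last_horizontal <- end_tangency && bead

  # chain vertices: walk the joint points
  p <- c(0, 0, z0)
  for (i in seq_len(n)) {
    tangent <- c(0, 0, 1)
    if ((i == 1 && first_horizontal) || (i == n && last_horizontal)) {
      tangent <- c(1, 0, 0)
      quat[i, ] <- q_xplus
    }
    pos[i, ] <- p + tangent / 2
    p <- p + tangent
  }

  shape <- tibble::tibble(type = rep("capsule", nb),
                          radius = rep(radius, nb),
                          length = rep(1, nb))
  mass <- rep(1, nb)
  inertia <- matrix(rep(capsule_inertia(1, radius, 1), each = nb), nb, 3)

  bead_index <- NA_integer_
  if (bead) {
    bead_index <- nb
    Rb <- bead_radius_nm / units$b_nm
    last_t <- quat_rotate(quat[n, ], c(0, 0, 1))
    attach <- p                      # end of last cylinder
    # bead sits on top of the attachment point
    pos[nb, ] <- attach + c(0, 0, Rb)
    shape$type[nb] <- "sphere"
    shape$radius[nb] <- Rb
    shape$length[nb] <- 2 * Rb
    mass[nb] <- bead_mass
    inertia[nb, ] <- rep(2 / 5 * bead_mass * Rb^2, 3)
  }

  state <- chain_state(pos, quat, mass = mass, inertia = inertia,
                       shape = shape)

  # joints: optional anchor, chain balls, optional bead weld
  type <- character(0); a <- integer(0); b <- integer(0)
  aa <- NULL; ab <- NULL; qr <- NULL
  add_joint <- function(ty, ia, ib, pa, pb, q = c(1, 0, 0, 0)) {
    type <<- c(type, ty); a <<- c(a, ia); b <<- c(b, ib)
    aa <<- rbind(aa, pa); ab <<- rbind(ab, pb); qr <<- rbind(qr, q)
  }
  if (anchor != "none") {
    # world anchor at the start of the first cylinder
    start_pt <- pos[1, ] - quat_rotate(quat[1, ], c(0, 0, 0.5))
    qref <- quat[1, ]   # q_a^-1 q_b with a = world
    add_joint(if (anchor == "weld") "weld" else "ball", 0L, 1L,
              start_pt, c(0, 0, -0.5), qref)
  }
  for (i in seq_len(n - 1)) {
    add_joint("ball", i, i + 1L, c(0, 0, 0.5), c(0, 0, -0.5))
  }
  if (bead) {
    Rb <- shape$radius[nb]
    qref <- quat_multiply(quat_conjugate(quat[n, ]), quat[nb, ])
    add_joint("weld", n, bead_index, c(0, 0, 0.5), c(0, 0, -Rb), qref)
  }
  joints <- joint_table(type, a, b, aa, ab, qr)

  structure(list(
    state = state, joints = joints, elastic = el, units = units,
    n_cylinders = n, bead_index = bead_index, anchor = anchor,
    radius = radius, end_tangency = end_tangency,
    L0 = n, Lk0 = n,
    phi_cum = rep(0, n - 1), phi_prev = rep(0, n - 1), phi_init = FALSE,
    psi = 0, psi_target = 0
  ), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d cylinders (r = %.3g b)%s, anchor = %s\n",
              x$n_cylinders, x$radius,
              if (!is.na(x$bead_index)) " + bead" else "", x$anchor))
  cat(sprintf("  L0 = %d b (%.3g nm), Lk0 = %d, g_b = %.3g, g_t = %.3g kBT\n",
              x$L0, x$L0 * x$units$b_nm, x$Lk0, x$elastic$g_b, x$elastic$g_t))
  invisible(x)
}

#' Count degrees of freedom of an assembly
#'
#' `n_dof = 6 N - m` with `m` the number of non-redundant holonomic
#' constraint rows of the permanent joints: 3 per ball joint, 6 per weld,
#' plus the bead clamp rows of the active protocol (3 for a turn clamp, 2
#' for the tilt lock of a torque clamp).
#'
#' @param assembly an [build_assembly()] object.
#' @param clamp_mode `"none"`, `"turn"` or `"torque"`.
#' @export
count_dof <- function(assembly, clamp_mode = c("none", "turn", "torque")) {
  clamp_mode <- match.arg(clamp_mode)
  m <- sum(joint_rows(assembly$joints)) +
    switch(clamp_mode, none = 0L, turn = 3L, torque = 2L)
  6L * n_bodies(assembly$state) - m
}

#' Draw thermal velocities for an assembly
#'
#' Initializes body velocities from the Maxwell distribution (linear
#' components `N(0, kBT/m)`, angular body-frame components `N(0, kBT/I_k)`
#' rotated to world). The draw ignores the constraints; the first solver
#' step projects the velocities onto the constraint manifold.
#'
#' @param assembly an assembly.
#' @param kBT thermal energy.
#' @param seed RNG seed (R stream).
#' @export
thermal_velocities <- function(assembly, kBT = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- assembly$state
  n <- n_bodies(st)
  for (i in seq_len(n)) {
    st$vel[i, ] <- stats::rnorm(3, sd = sqrt(kBT / st$mass[i]))
    wb <- stats::rnorm(3, sd = sqrt(kBT / st$inertia[i, ]))
    st$angvel[i, ] <- quat_rotate(st$quat[i, ], wb)
  }
  assembly$state <- st
  assembly
}

#' Draw a chain configuration from the Boltzmann distribution
#'
#' Replaces the assembly's geometry with an exact equilibrium draw. Two
#' cases admit direct sampling:
#' * `g_b = 0` (freely jointed limit): under a stretching force `f` along
#'   z the segment orientations are independent with density
#'   `exp(f b cos(theta) / kBT)` on the sphere -- sampled by inverse CDF at
#'   any force.
#' * `g_b > 0` at zero force: the joint angles form a Markov chain with
#'   per-joint density `exp(-g_b (1 - cos(theta)))` on the sphere (and
#'   independent twist `exp(-g_t (1 - cos(phi)))`), sampled joint by joint.
#'
#' Positions are rebuilt by walking the joints (all bearings coincide
#' exactly) and velocities are redrawn from the Maxwell distribution.
#' Starting production runs from such a draw removes the slow
#' configurational equilibration entirely; only velocities and local modes
#' need a short relaxation.
#'
#' @param assembly a chain assembly without bead (`anchor` "ball" or
#'   "none"; the exact draws are not available for welded/tangent builds).
#' @param force stretching force (kBT/b units); must be 0 unless
#'   `g_b = 0`.
#' @param kBT thermal energy.
#' @param seed R RNG seed.
#' @return the assembly with resampled configuration and velocities.
#' @export
sample_chain_configuration <- function(assembly, force = 0, kBT = 1,
                                       seed = NULL) {
  if (!is.na(assembly$bead_index) || assembly$anchor == "weld") {
    stop("sample_chain_configuration(): exact draws need a bead-free, ",
         "non-welded assembly", call. = FALSE)
  }
  gb <- assembly$elastic$g_b / kBT
  gt <- assembly$elastic$g_t / kBT
  if (gb > 0 && force != 0) {
    stop("sample_chain_configuration(): with bending rigidity the exact ",
         "draw is only available at zero force", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- assembly$n_cylinders
  st <- assembly$state

  # inverse-CDF draw of cos(angle) with density exp(a * cos) on the sphere
  rcos_tilt <- function(a) {
    u <- stats::runif(1)
    if (abs(a) < 1e-9) return(2 * u - 1)
    log(exp(-a) + u * (exp(a) - exp(-a))) / a
  }

  q <- c(1, 0, 0, 0)
  p <- c(0, 0, 0)
  for (i in seq_len(n)) {
    if (gb == 0) {
      # independent tilt relative to the force axis (z), uniform azimuth
      # and spin
      ct <- max(-1, min(1, rcos_tilt(force)))
      q <- quat_multiply(
        quat_from_axis_angle(c(0, 0, 1), stats::runif(1, 0, 2 * pi)),
        quat_from_axis_angle(c(0, 1, 0), acos(ct)))
      q <- quat_normalize(
        quat_multiply(q, quat_from_axis_angle(c(0, 0, 1),
                                              stats::runif(1, 0, 2 * pi))))
    } else if (i > 1) {
      # Markov step: bend (sphere measure) then twist (von Mises, flat
      # angle measure, simple rejection)
      ct <- 1 + log(stats::runif(1) * (1 - exp(-2 * gb)) + exp(-2 * gb)) / gb
      bend_az <- stats::runif(1, 0, 2 * pi)
      tw <- if (gt > 0) {
        repeat {
          cand <- stats::runif(1, -pi, pi)
          if (stats::runif(1) < exp(gt * (cos(cand) - 1))) break
        }
        cand
      } else stats::runif(1, -pi, pi)
      dq <- quat_multiply(
        quat_from_axis_angle(c(0, 0, 1), bend_az),
        quat_from_axis_angle(c(0, 1, 0), acos(max(-1, min(1, ct)))))
      dq <- quat_multiply(dq, quat_from_axis_angle(c(0, 0, 1), tw - bend_az))
      q <- quat_normalize(quat_multiply(q, dq))
    }
    tangent <- quat_rotate(q, c(0, 0, 1))
    st$quat[i, ] <- q
    st$pos[i, ] <- p + tangent / 2
    p <- p + tangent
  }
  assembly$state <- st
  assembly <- thermal_velocities(assembly, kBT = kBT)
  # reset twist bookkeeping to the new geometry
  assembly$phi_cum <- rep(0, n - 1)
  assembly$phi_prev <- rep(0, n - 1)
  assembly$phi_init <- FALSE
  assembly
}

#' Deterministic test fixtures
#'
#' Small scenes with pinned geometry used throughout the test-suite:
#' \describe{
#'   \item{`fixture_chain4()`}{four cylinders, ball-anchored to the origin --
#'     the minimal serial chain whose constraint matrix is block
#'     tridiagonal.}
#'   \item{`fixture_free_chain(n)`}{free chain, no anchor, no bead.}
#'   \item{`fixture_hairpin(n_arm)`}{two parallel arms one cylinder length
#'     apart joined by a cap segment; with the default effective radius the
#'     arms overlap and the first collision pass yields contacts.}
#'   \item{`fixture_micro_assembly()`}{four cylinders with plane anchor and
#'     bead -- the smallest full tweezers build.}
#' }
#' @param n,n_arm chain sizes.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_chain4 <- function() {
  build_assembly(4, anchor = "ball", bead = FALSE, salt_mM = 100)
}

#' @rdname fixtures
#' @export
fixture_free_chain <- function(n = 50) {
  build_assembly(n, anchor = "none", bead = FALSE, salt_mM = 100)
}

#' @rdname fixtures
#' @export
fixture_micro_assembly <- function() {
  build_assembly(4, anchor = "weld", bead = TRUE, salt_mM = 100,
                 bead_radius_nm = 10)
}

#' @rdname fixtures
#' @export
fixture_hairpin <- function(n_arm = 6) {
  # two-segment cap: arms 2 b apart; the low-salt effective radius
  # (2r ~ 2.4 b) makes the arms overlap by a fraction of a radius
  asm <- build_assembly(2L * n_arm + 2L, anchor = "none", bead = FALSE,
                        salt_mM = 10)
  n <- asm$n_cylinders
  st <- asm$state
  q_up <- c(1, 0, 0, 0)
  q_x <- quat_from_axis_angle(c(0, 1, 0), pi / 2)
  q_down <- quat_from_axis_angle(c(1, 0, 0), pi)
  p <- c(0, 0, 0)
  for (i in seq_len(n)) {
    if (i <= n_arm) { tangent <- c(0, 0, 1); st$quat[i, ] <- q_up }
    else if (i <= n_arm + 2) { tangent <- c(1, 0, 0); st$quat[i, ] <- q_x }
    else { tangent <- c(0, 0, -1); st$quat[i, ] <- q_down }
    st$pos[i, ] <- p + tangent / 2
    p <- p + tangent
  }
  asm$state <- st
  asm
}
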