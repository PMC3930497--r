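#' Evaluate joint constraint functions
#'
#' For each ball joint, the 3-vector separation of the two joint bearings
#' (world anchor of side `a` minus world anchor of side `b`); a perfectly
#' assembled joint gives exactly zero. Weld joints additionally contribute a
#' 3-component orientation error: the axis-angle vector of the relative
#' rotation away from the joint's reference orientation.
#'
#' @param state a [chain_state()].
#' @param joints a [joint_table()].
#' @return numeric vector of stacked constraint components (3 per ball
#'   joint, 6 per weld).
#' @export
evaluate_constraints <- function(state, joints) {
  out <- numeric(0)
  for (k in seq_len(nrow(joints))) {
    pa <- anchor_world(state, joints$a[k], c(joints$ax[k], joints$ay[k], joints$az[k]))
    pb <- anchor_world(state, joints$b[k], c(joints$bx[k], joints$by[k], joints$bz[k]))
    out <- c(out, pa - pb)
    if (joints$type[k] == "weld") {
      out <- c(out, weld_orientation_error(state, joints, k))
    }
  }
  out
}

# axis-angle orientation error of weld joint k: rotation taking the current
# relative orientation to the stored reference, expressed in world frame
weld_orientation_error <- function(state, joints, k) {
  qa <- if (joints$a[k] == 0L) c(1, 0, 0, 0) else state$quat[joints$a[k], ]
  qb <- state$quat[joints$b[k], ]
  qref <- c(joints$qw[k], joints$qx[k], joints$qy[k], joints$qz[k])
  # error quaternion: how far q_a^-1 q_b has drifted from qref
  qerr <- quat_multiply(quat_multiply(qa, qref), quat_conjugate(qb))
  if (qerr[1] < 0) qerr <- -qerr
  v <- qerr[2:4]
  s <- sqrt(sum(v^2))
  ang <- 2 * atan2(s, qerr[1])
  if (s < 1e-12) return(c(0, 0, 0))
  ang * v / s   # oriented so that dC/dt = omega_a - omega_b to first order
}

#' Assemble the constraint Jacobian
#'
#' Builds the dense Jacobian `J` with `dC/dt = J u` for the current state:
#' ball rows use blocks `(+I3, -skew(r_a))` on body `a` and `(-I3, +skew(r_b))`
#' on body `b`, with `r` the world lever arm from the centre of mass to the
#' bearing; weld orientation rows use `(omega_a - omega_b)`; contact rows are
#' single rows along the contact normal (see [contact_rows()]).
#'
#' @param state a [chain_state()].
#' @param joints a [joint_table()].
#' @param contacts optional list of contacts from [detect_contacts()].
#' @return dense matrix with 6N columns.
#' @export
assemble_jacobian <- function(state, joints, contacts = NULL) {
  n <- n_bodies(state)
  m <- sum(joint_rows(joints)) + length(contacts)
  J <- matrix(0, m, 6 * n)
  row <- 0L
  put <- function(J, row, body, lin, ang) {
    if (body > 0L) {
      o <- 6 * (body - 1)
      J[row, o + 1:3] <- J[row, o + 1:3] + lin
      J[row, o + 4:6] <- J[row, o + 4:6] + ang
    }
    J
  }
  for (k in seq_len(nrow(joints))) {
    a <- joints$a[k]; b <- joints$b[k]
    ra <- if (a == 0L) c(0, 0, 0) else
      quat_rotate(state$quat[a, ], c(joints$ax[k], joints$ay[k], joints$az[k]))
    rb <- quat_rotate(state$quat[b, ], c(joints$bx[k], joints$by[k], joints$bz[k]))
    for (d in 1:3) {
      row <- row + 1L
      e <- c(0, 0, 0); e[d] <- 1
      J <- put(J, row, a, e, -skew3(ra)[d, ])
      J <- put(J, row, b, -e, skew3(rb)[d, ])
    }
    if (joints$type[k] == "weld") {
      for (d in 1:3) {
        row <- row + 1L
        e <- c(0, 0, 0); e[d] <- 1
        J <- put(J, row, a, c(0, 0, 0), e)
        J <- put(J, row, b, c(0, 0, 0), -e)
      }
    }
  }
  for (ct in contacts) {
    row <- row + 1L
    nrm <- ct$normal
    J <- put(J, row, ct$body_1, nrm, cross3(ct$r1, nrm))
    J <- put(J, row, ct$body_2, -nrm, -cross3(ct$r2, nrm))
  }
  J
}

#' Build the velocity-level constraint system
#'
#' Forms `A = J W^{-1} J^T + diag(cfm)/dt` and the right-hand side of the
#' force-form system `A lambda = rhs`, whose solution, applied as
#' `u' = u + dt W^{-1} (F_ext + J^T lambda)`, drives the constraint velocity
#' toward `v_target - (erp/dt) C`. With the returned `lambda` the residual
#' identity `J u' + (erp/dt) C - v_target + cfm * lambda = 0` holds to solver
#' precision; `cfm > 0` makes `A` strictly positive definite.
#'
#' @param J constraint Jacobian.
#' @param W generalized mass matrix.
#' @param F_ext generalized external force (length 6N).
#' @param u generalized velocity at time t.
#' @param dt timestep (> 0).
#' @param erp error-reduction parameter in `[0, 1]`.
#' @param cfm constraint-force-mixing value(s), `>= 0` (scalar or per row).
#' @param C constraint values matching the rows of `J`.
#' @param v_target per-row target constraint velocity (default 0; used by
#'   kinematic clamps and contact push-out).
#' @param lo,hi per-row bounds on lambda (defaults unbounded).
#' @return list with `A`, `rhs`, `lo`, `hi` and the ingredients needed to
#'   apply the solution.
#' @export
build_system <- function(J, W, F_ext, u, dt, erp, cfm, C,
                         v_target = 0, lo = -Inf, hi = Inf) {
  if (dt <= 0) stop("build_system(): dt must be positive", call. = FALSE)
  if (erp < 0 || erp > 1) stop("build_system(): erp must lie in [0, 1]", call. = FALSE)
  if (any(cfm < 0)) stop("build_system(): cfm must be >= 0", call. = FALSE)
  m <- nrow(J)
  Winv <- solve(W)
  A <- J %*% Winv %*% t(J) + diag(rep(cfm, length.out = m) / dt, m)
  uf <- u + dt * (Winv %*% F_ext)        # unconstrained velocity update
  rhs <- as.numeric(rep(v_target, length.out = m) - (erp / dt) * C - J %*% uf) / dt
  list(A = A, rhs = rhs, lo = rep(lo, length.out = m),
       hi = rep(hi, length.out = m), Winv = Winv, uf = as.numeric(uf),
       J = J, dt = dt, cfm = rep(cfm, length.out = m))
}

#' Exact O(N) solution for an anchored serial chain
#'
#' For a serial chain of ball joints (no contacts) the matrix
#' `A = J W^{-1} J^T` is block tridiagonal with 3x3 blocks; the system is
#' solved exactly by block forward elimination and back substitution in one
#' O(N) sweep. Blocks may also be supplied with heterogeneous sizes (welds,
#' clamp rows grouped with their joint).
#'
#' @param D list of diagonal blocks (square matrices).
#' @param E list of super-diagonal blocks, `E[[g]]` coupling group `g` to
#'   `g+1` (`length(D) - 1` entries).
#' @param rhs right-hand side, length `sum(sizes)`.
#' @return lambda solving the block-tridiagonal system.
#' @export
solve_block_tridiagonal <- function(D, E, rhs) {
  G <- length(D)
  sizes <- vapply(D, nrow, 1L)
  stopifnot(length(E) == G - 1, length(rhs) == sum(sizes))
  off <- cumsum(c(0, sizes))
  Dt <- vector("list", G)
  y <- vector("list", G)
  Dt[[1]] <- D[[1]]
  y[[1]] <- rhs[off[1] + seq_len(sizes[1])]
  for (g in 2:G) {
    Lg <- t(E[[g - 1]]) %*% solve(Dt[[g - 1]])
    Dt[[g]] <- D[[g]] - Lg %*% E[[g - 1]]
    y[[g]] <- rhs[off[g] + seq_len(sizes[g])] - Lg %*% y[[g - 1]]
  }
  lam <- vector("list", G)
  lam[[G]] <- solve(Dt[[G]], y[[G]])
  for (g in (G - 1):1) {
    lam[[g]] <- solve(Dt[[g]], y[[g]] - E[[g]] %*% lam[[g + 1]])
  }
  unlist(lam)
}

#' Exact chain solve from a dense block-tridiagonal matrix
#'
#' Convenience wrapper for the serial-chain case: partitions a dense `A`
#' into consecutive blocks of the given sizes (3 for ball joints) and calls
#' [solve_block_tridiagonal()]. Off-band blocks must be zero; this is
#' asserted, since a contact row would violate the serial-chain contract.
#'
#' @param A dense block-tridiagonal SPD matrix.
#' @param rhs right-hand side.
#' @param sizes block sizes (default all 3).
#' @export
solve_chain_exact <- function(A, rhs, sizes = NULL) {
  m <- nrow(A)
  if (is.null(sizes)) sizes <- rep(3L, m / 3)
  stopifnot(sum(sizes) == m)
  off <- cumsum(c(0, sizes))
  G <- length(sizes)
  # contract check: no coupling outside the tridiagonal band
  if (G > 2) {
    for (g in 1:(G - 2)) {
      blk <- A[off[g] + seq_len(sizes[g]), (off[g + 2] + 1):m, drop = FALSE]
      if (any(blk != 0)) {
        stop("solve_chain_exact(): matrix is not block tridiagonal ",
             "(contacts present?)", call. = FALSE)
      }
    }
  }
  D <- lapply(seq_len(G), function(g)
    A[off[g] + seq_len(sizes[g]), off[g] + seq_len(sizes[g]), drop = FALSE])
  E <- if (G > 1) lapply(seq_len(G - 1), function(g)
    A[off[g] + seq_len(sizes[g]), off[g + 1] + seq_len(sizes[g + 1]), drop = FALSE])
  else list()
  solve_block_tridiagonal(D, E, rhs)
}

#' Projected successive over-relaxation solver
#'
#' SOR sweeps over the rows of `A lambda = rhs`, projecting bounded rows
#' onto `[lo, hi]` after each update (projected Gauss-Seidel for
#' `omega = 1`). For SPD `A` and unbounded rows the iterates converge to the
#' exact solution; bounded rows satisfy their bounds after every sweep.
#'
#' @param A SPD matrix (or matrix-free operator not supported here; the
#'   compiled engine has its own matrix-free version).
#' @param rhs right-hand side.
#' @param lo,hi per-row bounds.
#' @param omega relaxation factor in (0, 2).
#' @param n_iter number of sweeps.
#' @param lambda0 optional warm start.
#' @export
solve_sor <- function(A, rhs, lo = -Inf, hi = Inf, omega = 1.3, n_iter = 64,
                      lambda0 = NULL) {
  if (omega <= 0 || omega >= 2) {
    stop("solve_sor(): omega must lie in (0, 2)", call. = FALSE)
  }
  m <- length(rhs)
  lo <- rep(lo, length.out = m); hi <- rep(hi, length.out = m)
  lam <- if (is.null(lambda0)) numeric(m) else lambda0
  d <- diag(A)
  for (it in seq_len(n_iter)) {
    for (i in seq_len(m)) {
      r <- rhs[i] - sum(A[i, ] * lam)
      lam[i] <- min(max(lam[i] + omega * r / d[i], lo[i]), hi[i])
    }
  }
  lam
}

#' Direct solver with bound constraints
#'
#' Unbounded rows are solved by Cholesky factorization; with unilateral
#' (contact) rows present, an active-set iteration over the bounded rows
#' finds the mixed-complementarity solution: at convergence each bounded row
#' either sits strictly inside its bounds with zero residual or at a bound
#' with a residual pushing it outward. Always converges for SPD `A`.
#'
#' @inheritParams solve_sor
#' @param max_pivots safety cap on active-set changes.
#' @export
solve_direct <- function(A, rhs, lo = -Inf, hi = Inf, max_pivots = 200) {
  m <- length(rhs)
  lo <- rep(lo, length.out = m); hi <- rep(hi, length.out = m)
  ch <- tryCatch(chol(A), error = function(e)
    stop("solve_direct(): matrix is not SPD: ", conditionMessage(e), call. = FALSE))
  bounded <- which(is.finite(lo) | is.finite(hi))
  if (length(bounded) == 0) {
    return(backsolve(ch, forwardsolve(t(ch), rhs)))
  }
  # active set: rows clamped at a bound; start all bounded rows free
  clamped_lo <- rep(FALSE, m); clamped_hi <- rep(FALSE, m)
  for (it in seq_len(max_pivots)) {
    lam <- numeric(m)
    fixed <- clamped_lo | clamped_hi
    lam[clamped_lo] <- lo[clamped_lo]
    lam[clamped_hi] <- hi[clamped_hi]
    free <- which(!fixed)
    if (length(free) > 0) {
      r <- rhs[free] - A[free, fixed, drop = FALSE] %*% lam[fixed]
      lam[free] <- solve(A[free, free, drop = FALSE], r)
    }
    resid <- as.numeric(A %*% lam - rhs)
    viol_free <- free[free %in% bounded &
                        (lam[free] < lo[free] - 1e-12 | lam[free] > hi[free] + 1e-12)]
    # residual sign convention: at lo we need resid >= 0 to stay clamped
    rel_lo <- which(clamped_lo & resid < -1e-12)
    rel_hi <- which(clamped_hi & resid > 1e-12)
    if (length(viol_free) == 0 && length(rel_lo) == 0 && length(rel_hi) == 0) {
      return(lam)
    }
    for (i in viol_free) {
      if (lam[i] < lo[i]) clamped_lo[i] <- TRUE else clamped_hi[i] <- TRUE
    }
    clamped_lo[rel_lo] <- FALSE
    clamped_hi[rel_hi] <- FALSE
  }
  warning("solve_direct(): active-set iteration hit the pivot cap")
  lam
}

#' Solver dispatch scheme
#'
#' Routes a built system to the appropriate solver: with no collisions the
#' exact serial-chain solution is used; with collisions, SOR is run first and
#' its solution accepted only if the constraint-violation metric (worst
#' per-step bearing-separation growth implied by the residual) stays within
#' `accept_tol`, otherwise the step is re-solved with the direct solver.
#'
#' @param system a list from [build_system()].
#' @param has_collisions logical flag.
#' @param sor_params list with `omega` and `n_iter`.
#' @param accept_tol accepted per-step constraint-violation growth (length
#'   units; default `1e-6` b).
#' @param sizes block sizes for the exact path.
#' @return list `lambda`, `solver` ("exact", "sor" or "direct"), `violation`.
#' @export
dispatch_solver <- function(system, has_collisions, sor_params = list(),
                            accept_tol = 1e-6, sizes = NULL) {
  omega <- sor_params$omega %||% 1.3
  n_iter <- sor_params$n_iter %||% 64
  if (!has_collisions) {
    lam <- solve_chain_exact(system$A, system$rhs, sizes = sizes)
    return(list(lambda = lam, solver = "exact",
                violation = solution_violation(system, lam)))
  }
  lam <- solve_sor(system$A, system$rhs, system$lo, system$hi,
                   omega = omega, n_iter = n_iter)
  v <- solution_violation(system, lam)
  if (v <= accept_tol) {
    return(list(lambda = lam, solver = "sor", violation = v))
  }
  lam <- solve_direct(system$A, system$rhs, system$lo, system$hi)
  list(lambda = lam, solver = "direct",
       violation = solution_violation(system, lam))
}

# worst implied per-step growth of a bearing separation, in length units:
# the row residual is a velocity error divided by dt, so growth = dt^2 * |r|
# (complementarity-adjusted on rows clamped at a bound)
solution_violation <- function(system, lambda) {
  r <- as.numeric(system$A %*% lambda - system$rhs)
  at_lo <- is.finite(system$lo) & lambda <= system$lo + 1e-14
  at_hi <- is.finite(system$hi) & lambda >= system$hi - 1e-14
  # at an active lower bound a positive residual is the allowed multiplier
  # sign, not a violation (and symmetrically at an upper bound)
  r[at_lo] <- pmin(r[at_lo], 0)
  r[at_hi] <- pmax(r[at_hi], 0)
  max(abs(r)) * system$dt^2
}

#' Generalized constraint force
#'
#' By the principle of virtual work the joint reactions are `F_c = J^T
#' lambda`; for velocities satisfying `J u = 0` this force does no work.
#'
#' @param J constraint Jacobian.
#' @param lambda Lagrange multipliers.
#' @export
constraint_force <- function(J, lambda) as.numeric(t(J) %*% lambda)

`%||%` <- function(x, y) if (is.null(x)) y else x
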