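# Velocity-level constraint system: C, J, A, and the solver family.

dt0 <- 0.000592

test_that("constraint function is the bearing separation", {
  asm <- fixture_chain4()
  expect_equal(evaluate_constraints(asm$state, asm$joints),
               rep(0, 12))
  # translate body 3 by (eps, 0, 0): its two joints pick up -/+ eps with the
  # a - b sign convention
  eps <- 1e-3
  st <- asm$state
  st$pos[3, 1] <- st$pos[3, 1] + eps
  C <- evaluate_constraints(st, asm$joints)
  expect_equal(C[7], -eps)    # joint 3 (bodies 2-3): a - b = -eps
  expect_equal(C[10], eps)    # joint 4 (bodies 3-4): a - b = +eps
  # random perturbed chain vs direct coordinate computation
  asm2 <- random_perturbed_chain(6, seed = 3)
  C2 <- evaluate_constraints(asm2$state, asm2$joints)
  st2 <- asm2$state
  # direct route: world anchor positions from rotation matrices
  k <- 4   # joint between bodies 3 and 4 (after the anchor joint)
  Ra <- rotmat_rodrigues(st2$quat[3, ]); Rb <- rotmat_rodrigues(st2$quat[4, ])
  pa <- st2$pos[3, ] + Ra %*% c(0, 0, 0.5)
  pb <- st2$pos[4, ] + Rb %*% c(0, 0, -0.5)
  expect_lt(max(abs(C2[(k - 1) * 3 + 1:3] - as.numeric(pa - pb))), 1e-12)
})

test_that("Jacobian matches finite differences of C and J u = 0 at rest", {
  asm <- random_perturbed_chain(5, seed = 11)
  st <- asm$state
  J <- assemble_jacobian(st, asm$joints)
  u <- generalized_velocity(st)
  # finite-difference along the actual motion
  delta <- 1e-7
  st2 <- st
  st2$pos <- st$pos + delta * st$vel
  for (i in seq_len(n_bodies(st))) {
    st2$quat[i, ] <- exp_map_update(st$quat[i, ], st$angvel[i, ], delta)
  }
  dC <- (evaluate_constraints(st2, asm$joints) -
           evaluate_constraints(st, asm$joints)) / delta
  expect_equal(dC, as.numeric(J %*% u), tolerance = 1e-5)
  # rest
  st0 <- set_generalized_velocity(st, rep(0, 6 * n_bodies(st)))
  expect_equal(as.numeric(J %*% generalized_velocity(st0)),
               rep(0, nrow(J)))
})

test_that("anchored serial chain gives an exactly block-tridiagonal A", {
  asm <- fixture_chain4()
  st <- thermal_velocities(asm, seed = 2)$state
  J <- assemble_jacobian(st, asm$joints)
  W <- generalized_mass(st)
  A <- J %*% solve(W) %*% t(J)
  # zero blocks beyond the first off-diagonal band
  for (g in 1:2) {
    blk <- A[(g - 1) * 3 + 1:3, (g + 1) * 3 + 1:(12 - 3 * (g + 1)), drop = FALSE]
    expect_equal(max(abs(blk)), 0)
  }
})

test_that("build_system solution satisfies the velocity-level contract", {
  for (seed in 1:10) {
    n <- sample(3:7, 1)
    asm <- random_perturbed_chain(n, seed = 100 + seed)
    st <- asm$state
    u <- generalized_velocity(st)
    W <- generalized_mass(st)
    J <- assemble_jacobian(st, asm$joints)
    C <- evaluate_constraints(st, asm$joints)
    F <- rnorm(6 * n)
    erp <- 0.8; cfm <- 1e-10
    sys <- build_system(J, W, F, u, dt0, erp, cfm, C)
    lam <- solve(sys$A, sys$rhs)
    u_new <- sys$uf + dt0 * as.numeric(sys$Winv %*% constraint_force(J, lam))
    resid <- as.numeric(J %*% u_new) + (erp / dt0) * C + cfm * lam
    expect_lt(max(abs(resid)), 1e-8)
  }
  # trivial cases
  asm <- fixture_chain4()
  st <- asm$state
  J <- assemble_jacobian(st, asm$joints)
  W <- generalized_mass(st)
  C <- evaluate_constraints(st, asm$joints)
  sys <- build_system(J, W, rep(0, 24), rep(0, 24), dt0, 0.8, 1e-10, C)
  expect_equal(sys$rhs, rep(0, 12))
  expect_equal(solve(sys$A, sys$rhs), rep(0, 12))
  # erp = 0: rhs independent of C
  sysA <- build_system(J, W, rep(0, 24), rep(1, 24), dt0, 0, 1e-10, C)
  sysB <- build_system(J, W, rep(0, 24), rep(1, 24), dt0, 0, 1e-10, C + 5)
  expect_equal(sysA$rhs, sysB$rhs)
  expect_error(build_system(J, W, rep(0, 24), rep(0, 24), -1, 0.8, 0, C),
               "dt")
  expect_error(build_system(J, W, rep(0, 24), rep(0, 24), dt0, 2, 0, C),
               "erp")
  expect_error(build_system(J, W, rep(0, 24), rep(0, 24), dt0, 0.8, -1, C),
               "cfm")
})

test_that("exact chain solver agrees with a dense factorization", {
  for (n in c(2, 4, 16, 128)) {
    asm <- random_perturbed_chain(n, seed = n)
    st <- asm$state
    J <- assemble_jacobian(st, asm$joints)
    W <- generalized_mass(st)
    C <- evaluate_constraints(st, asm$joints)
    sys <- build_system(J, W, rnorm(6 * n), generalized_velocity(st),
                        dt0, 0.8, 1e-10, C)
    lam_dense <- solve(sys$A, sys$rhs)
    lam_exact <- solve_chain_exact(sys$A, sys$rhs)
    expect_lt(max(abs(lam_exact - lam_dense)),
              1e-10 * max(abs(lam_dense)))
    # and the compiled block-tridiagonal kernel agrees too
    sizes <- rep(3L, n)
    off <- cumsum(c(0, sizes))
    D <- lapply(seq_len(n), function(g) sys$A[off[g] + 1:3, off[g] + 1:3])
    E <- lapply(seq_len(n - 1), function(g) sys$A[off[g] + 1:3, off[g + 1] + 1:3])
    lam_cpp <- rbdna:::cpp_block_tridiag_solve(D, E, sys$rhs)
    expect_lt(max(abs(lam_cpp - lam_dense)), 1e-10 * max(abs(lam_dense)))
  }
  expect_equal(solve_chain_exact(diag(6) + 0, rep(0, 6)), rep(0, 6))
})

test_that("exact chain solver refuses non-tridiagonal systems and scales O(N)", {
  A <- diag(9); A[1, 9] <- A[9, 1] <- 0.5
  expect_error(solve_chain_exact(A, rep(1, 9)), "tridiagonal")
  # complexity smoke test: doubling N should not much more than double time
  mk <- function(n) {
    asm <- random_perturbed_chain(n, seed = n + 1)
    st <- asm$state
    J <- assemble_jacobian(st, asm$joints)
    sys <- build_system(J, generalized_mass(st), rep(0, 6 * n),
                        generalized_velocity(st), dt0, 0.8, 1e-10,
                        evaluate_constraints(st, asm$joints))
    sizes <- rep(3L, n); off <- cumsum(c(0, sizes))
    list(D = lapply(seq_len(n), function(g) sys$A[off[g] + 1:3, off[g] + 1:3]),
         E = lapply(seq_len(n - 1), function(g) sys$A[off[g] + 1:3, off[g + 1] + 1:3]),
         rhs = sys$rhs)
  }
  s1 <- mk(128); s2 <- mk(256)
  t1 <- system.time(for (k in 1:50) rbdna:::cpp_block_tridiag_solve(s1$D, s1$E, s1$rhs))[3]
  t2 <- system.time(for (k in 1:50) rbdna:::cpp_block_tridiag_solve(s2$D, s2$E, s2$rhs))[3]
  expect_lt(t2, max(t1, 0.02) * 4)   # generous: linear scaling, noisy timer
})

test_that("SOR converges monotonically in the A-norm and clamps bounds", {
  set.seed(5)
  M <- matrix(rnorm(900), 30)
  A <- crossprod(M) + diag(30)
  rhs <- rnorm(30)
  exact <- solve(A, rhs)
  anorm <- function(x) sqrt(sum((x - exact) * (A %*% (x - exact))))
  errs <- vapply(c(1, 5, 20, 80, 200), function(k)
    anorm(solve_sor(A, rhs, omega = 1.3, n_iter = k)), 1.0)
  expect_true(all(diff(errs) < 1e-12))
  expect_lt(errs[5] / anorm(rep(0, 30)), 1e-6)
  # diagonal system solves in one sweep at omega = 1
  D <- diag(runif(6, 1, 3))
  expect_equal(solve_sor(D, rhs[1:6], omega = 1, n_iter = 1),
               rhs[1:6] / diag(D), tolerance = 1e-12)
  # bounded rows stay clamped at 0 when pushed negative
  lam <- solve_sor(diag(2), c(-1, 1), lo = c(0, -Inf), hi = c(Inf, Inf),
                   omega = 1, n_iter = 10)
  expect_equal(lam, c(0, 1))
  expect_error(solve_sor(A, rhs, omega = 2.5), "omega")
})

test_that("direct solver solves mixed complementarity problems exactly", {
  # unbounded = dense solve
  set.seed(8)
  M <- matrix(rnorm(400), 20)
  A <- crossprod(M) + diag(20)
  rhs <- rnorm(20)
  expect_equal(solve_direct(A, rhs), solve(A, rhs), tolerance = 1e-10,
               ignore_attr = TRUE)
  # 1x1 separating contact
  expect_equal(solve_direct(matrix(2), -1, lo = 0), 0)
  # random mixed systems vs exhaustive enumeration
  for (seed in 1:8) {
    set.seed(seed)
    m <- 12
    M <- matrix(rnorm(m * m), m)
    A <- crossprod(M) + diag(m)
    rhs <- rnorm(m)
    bounded <- sort(sample(m, sample(3:8, 1)))
    lo <- rep(-Inf, m); lo[bounded] <- 0
    lam <- solve_direct(A, rhs, lo = lo)
    lam_oracle <- lcp_enumeration(A, rhs, bounded)
    expect_equal(lam, lam_oracle, tolerance = 1e-9)
    # KKT residuals
    resid <- as.numeric(A %*% lam - rhs)
    free <- lam > 1e-12 | !(seq_len(m) %in% bounded)
    expect_lt(max(abs(resid[free])), 1e-9)
    expect_true(all(resid[!free] >= -1e-9))
  }
  expect_error(solve_direct(matrix(c(1, 2, 2, 1), 2), c(1, 1)), "SPD")
})

test_that("dispatcher routes to the exact solver and falls back to direct", {
  asm <- random_perturbed_chain(6, seed = 21)
  st <- asm$state
  J <- assemble_jacobian(st, asm$joints)
  sys <- build_system(J, generalized_mass(st), rnorm(36),
                      generalized_velocity(st), dt0, 0.8, 1e-10,
                      evaluate_constraints(st, asm$joints))
  out <- dispatch_solver(sys, has_collisions = FALSE)
  expect_identical(out$solver, "exact")
  expect_equal(out$lambda, solve_chain_exact(sys$A, sys$rhs))
  # starved SOR on a stiff system falls back to the direct path
  out2 <- dispatch_solver(sys, has_collisions = TRUE,
                          sor_params = list(n_iter = 1), accept_tol = 1e-12)
  expect_identical(out2$solver, "direct")
  expect_lte(out2$violation, 1e-9)
  # healthy SOR is accepted
  out3 <- dispatch_solver(sys, has_collisions = TRUE,
                          sor_params = list(n_iter = 400), accept_tol = 1e-8)
  expect_identical(out3$solver, "sor")
})

test_that("constraint force obeys virtual work and Newton's third law", {
  asm <- random_perturbed_chain(5, seed = 31)
  st <- asm$state
  J <- assemble_jacobian(st, asm$joints)
  expect_equal(constraint_force(J, rep(0, nrow(J))), rep(0, 30))
  # u in the null space of J does no work against the constraint force
  ns <- MASS::Null(t(J))
  lam <- rnorm(nrow(J))
  Fc <- constraint_force(J, lam)
  for (k in seq_len(min(3, ncol(ns)))) {
    expect_lt(abs(sum(Fc * ns[, k])), 1e-10)
  }
  # third law: per-joint force blocks on the two bodies cancel
  # (linear parts; joints 2..: bodies (k-1, k))
  for (jk in 2:5) {
    rows <- (jk - 1) * 3 + 1:3
    lamk <- numeric(nrow(J)); lamk[rows] <- rnorm(3)
    Fk <- matrix(constraint_force(J, lamk), ncol = 6, byrow = TRUE)
    forces <- Fk[, 1:3]
    expect_equal(colSums(forces), c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("a bearing separation decays geometrically by (1 - erp) per step", {
  for (erp in c(0.2, 0.8, 1.0)) {
    asm <- fixture_chain4()
    st <- asm$state
    st$pos[3, ] <- st$pos[3, ] + c(2e-4, 0, 0)   # artificial separation
    c0 <- max(abs(evaluate_constraints(st, asm$joints)))
    st1 <- step_state(st, rep(0, 24), asm$joints, dt0,
                      solver_params(erp = erp))
    c1 <- max(abs(evaluate_constraints(st1, asm$joints)))
    expect_equal(c1 / c0, 1 - erp, tolerance = 0.02)
  }
})
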