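# Local Langevin and global velocity-rescaling thermostats.

dt0 <- 0.000592

test_that("local noise amplitudes satisfy the discrete FDT", {
  # single body at rest: forces are pure noise; sample covariance of the
  # linear components must be 2 gamma kBT m / dt per component
  st <- random_state(1, 1)
  st$vel[] <- 0; st$angvel[] <- 0
  st$quat[1, ] <- c(1, 0, 0, 0)
  par <- thermostat_params("local", gamma = 10, kBT = 1.5)
  set.seed(42)
  draws <- t(replicate(20000, local_langevin_force(st, par, dt0)[1:3]))
  v_target <- 2 * 10 * 1.5 * 1 / dt0
  expect_equal(apply(draws, 2, stats::var) / v_target, rep(1, 3),
               tolerance = 0.05)
  expect_equal(colMeans(draws) / sqrt(v_target), rep(0, 3),
               tolerance = 0.05)
  # angular: per principal axis variance 2 gamma kBT I_k / dt (body frame;
  # with identity orientation world = body)
  draws_w <- t(replicate(20000, local_langevin_force(st, par, dt0)[4:6]))
  w_target <- 2 * 10 * 1.5 * st$inertia[1, ] / dt0
  expect_equal(apply(draws_w, 2, stats::var) / w_target, rep(1, 3),
               tolerance = 0.05)
})

test_that("kBT = 0 reduces the local thermostat to pure friction", {
  asm <- quiet_build(2, anchor = "none", bead = FALSE, g_b = 0, g_t = 0)
  asm$state$vel[1, ] <- c(1, 0, 0)
  gam <- 10
  r <- run_simulation(asm, 2000, thermostat = thermostat_params("local", gamma = gam, kBT = 0),
                      seed = 1, collisions = FALSE, obs_stride = 2000,
                      wr_stride = 0)
  t_end <- 2000 * dt0
  expect_equal(r$assembly$state$vel[1, 1], exp(-gam * t_end),
               tolerance = 0.01)
})

test_that("a free body thermalizes to equipartition under the local thermostat", {
  # 3/2 kBT in translation and in rotation
  asm <- quiet_build(2, anchor = "none", bead = FALSE, g_b = 0, g_t = 0)
  asm$joints <- asm$joints[0, ]
  r <- run_simulation(asm, 4e5, thermostat = thermostat_params("local"),
                      seed = 3, collisions = FALSE, obs_stride = 100,
                      wr_stride = 0)
  K <- r$observables$E_kin[-(1:300)]
  expect_equal(mean(K), 6, tolerance = 0.02)      # 2 bodies x 6 dof / 2
})

test_that("global thermostat force is exactly parallel to the momentum", {
  par <- thermostat_params("global", gamma = 10)
  for (seed in 1:10) {
    st <- random_state(4, seed)
    out <- global_thermostat_force(st, par, n_dof = 24, dt = dt0)
    P <- as.numeric(generalized_mass(st) %*% generalized_velocity(st))
    # angle between force and P
    cosang <- sum(out$force * P) / sqrt(sum(out$force^2) * sum(P^2))
    expect_equal(abs(cosang), 1, tolerance = 1e-12)
  }
  # cold start returns zero force
  st0 <- random_state(3, 1)
  st0$vel[] <- 0; st0$angvel[] <- 0
  out0 <- global_thermostat_force(st0, par, n_dof = 18, dt = dt0)
  expect_equal(out0$force, rep(0, 18))
})

test_that("global force never disturbs satisfied constraints", {
  asm <- fixture_chain4()
  # velocities satisfying J u = 0: project a random u
  st <- asm$state
  J <- assemble_jacobian(st, asm$joints)
  W <- generalized_mass(st)
  u <- rnorm(24)
  Winv <- solve(W)
  A <- J %*% Winv %*% t(J)
  u <- u - Winv %*% t(J) %*% solve(A, J %*% u)
  st <- set_generalized_velocity(st, as.numeric(u))
  expect_lt(max(abs(J %*% generalized_velocity(st))), 1e-12)
  par <- thermostat_params("global")
  set.seed(5)
  out <- global_thermostat_force(st, par, n_dof = count_dof(asm), dt = dt0)
  expect_lt(thermostat_constraint_decoupling_check(st, out$force, asm$joints),
            1e-10)
  # contrast: the local force generically disturbs the constraints
  set.seed(5)
  fl <- local_langevin_force(st, thermostat_params("local"), dt0)
  expect_gt(thermostat_constraint_decoupling_check(st, fl, asm$joints), 1)
  # residual scales linearly with an injected violation (same rescaling
  # draw each time so only the violation varies)
  res <- vapply(c(1e-6, 1e-5, 1e-4), function(eps) {
    stv <- set_generalized_velocity(st, as.numeric(u) + eps * rep(1, 24))
    set.seed(99)
    outv <- global_thermostat_force(stv, par, n_dof = count_dof(asm), dt = dt0)
    thermostat_constraint_decoupling_check(stv, outv$force, asm$joints)
  }, 1.0)
  expect_equal(res[2] / res[1], 10, tolerance = 0.05)
  expect_equal(res[3] / res[2], 10, tolerance = 0.05)
})

test_that("kinetic energy autocorrelation time under the local thermostat is 1/(2 gamma)", {
  # an OU velocity with friction gamma has <v(0)v(t)> ~ exp(-gamma t), so
  # the kinetic-energy correlation decays as exp(-2 gamma t)
  asm <- quiet_build(2, anchor = "none", bead = FALSE, g_b = 0, g_t = 0)
  asm$joints <- asm$joints[0, ]
  gam <- 10
  r <- run_simulation(asm, 6e5, thermostat = thermostat_params("local", gamma = gam),
                      seed = 9, collisions = FALSE, obs_stride = 10,
                      wr_stride = 0)
  K <- r$observables$E_kin[-(1:1000)]
  ac <- autocorrelation(K, max_lag = 200, dt_sample = 10 * dt0)
  tau <- fit_relaxation_time(ac, fit_floor = 0.2)$tau
  expect_equal(tau, 1 / (2 * gam), tolerance = 0.2)
})

test_that("both thermostats sample the same end-to-end distribution", {
  # 50-cylinder free chain. Independent replicas, each started from its own
  # exact Boltzmann draw, give i.i.d. end-to-end samples for both
  # thermostats (the slow collective modes of a single long run would
  # otherwise make a KS test meaningless).
  asm <- fixture_free_chain(50)
  e2e_of <- function(a) {
    st <- a$state
    p0 <- st$pos[1, ] - quat_rotate(st$quat[1, ], c(0, 0, 0.5))
    pe <- st$pos[50, ] + quat_rotate(st$quat[50, ], c(0, 0, 0.5))
    sqrt(sum((pe - p0)^2))
  }
  one <- function(mode, k) {
    s <- sample_chain_configuration(asm, seed = 3000 + k)
    r <- run_simulation(s, 3e4, thermostat = thermostat_params(mode),
                        seed = 100 * k + (mode == "local"),
                        collisions = FALSE, obs_stride = 3e4, wr_stride = 0)
    e2e_of(r$assembly)
  }
  eg <- vapply(1:25, function(k) one("global", k), 1.0)
  el <- vapply(1:25, function(k) one("local", 1000 + k), 1.0)
  ks <- suppressWarnings(stats::ks.test(eg, el))
  expect_gt(ks$p.value, 0.01)
  # and both agree with the exact configurational sampler
  eref <- vapply(1:200, function(k)
    e2e_of(sample_chain_configuration(asm, seed = 8000 + k)), 1.0)
  expect_gt(suppressWarnings(stats::ks.test(eg, eref))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(el, eref))$p.value, 0.01)
})
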