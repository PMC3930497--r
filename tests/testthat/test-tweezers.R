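# Assembly construction, effective radius, degrees of freedom, protocols.

test_that("effective radius follows the Debye screening length", {
  # lambda_D(1 mol/L) = 0.304 nm
  expect_equal(effective_radius(1000) - 1, 0.304, tolerance = 1e-12)
  # monotone decreasing in salt
  salts <- c(1, 5, 10, 50, 100, 500, 1000)
  r <- effective_radius(salts)
  expect_true(all(diff(r) < 0))
  # the two standard buffers
  expect_equal(effective_radius(100), 1 + 0.304 / sqrt(0.1), tolerance = 1e-12)
  expect_equal(effective_radius(10), 1 + 0.304 / sqrt(0.01), tolerance = 1e-12)
  expect_error(effective_radius(-5), "positive")
})

test_that("assemblies are built exactly closed and in static equilibrium", {
  asm <- quiet_build(4, anchor = "weld", bead = TRUE, bead_radius_nm = 10)
  expect_equal(evaluate_constraints(asm$state, asm$joints),
               rep(0, nrow(asm$joints) * 0 + length(evaluate_constraints(asm$state, asm$joints))))
  expect_equal(max(abs(evaluate_constraints(asm$state, asm$joints))), 0)
  # contour length
  asm2 <- quiet_build(17, anchor = "none", bead = FALSE)
  p0 <- asm2$state$pos[1, ] - quat_rotate(asm2$state$quat[1, ], c(0, 0, 0.5))
  pe <- asm2$state$pos[17, ] + quat_rotate(asm2$state$quat[17, ], c(0, 0, 0.5))
  expect_equal(sqrt(sum((pe - p0)^2)), 17)
  expect_equal(asm2$L0, 17)
  expect_equal(asm2$Lk0, 17)
  # static equilibrium: one thermostat-free step leaves it at rest
  r <- run_simulation(asm, 1, thermostat = thermostat_params("off"),
                      seed = 1, collisions = FALSE, obs_stride = 1,
                      wr_stride = 0)
  expect_lt(max(abs(r$assembly$state$vel)), 1e-10)
  expect_lt(max(abs(r$assembly$state$angvel)), 1e-10)
  expect_error(build_assembly(1), "at least 2")
})

test_that("tangent-end builds start tangent to their attachment surfaces", {
  asm <- quiet_build(6, anchor = "weld", bead = TRUE, bead_radius_nm = 10,
                     end_tangency = TRUE)
  t1 <- quat_rotate(asm$state$quat[1, ], c(0, 0, 1))
  tn <- quat_rotate(asm$state$quat[6, ], c(0, 0, 1))
  expect_equal(t1[3], 0, tolerance = 1e-12)   # parallel to the plane
  expect_equal(tn[3], 0, tolerance = 1e-12)   # tangent to the bead surface
  expect_equal(max(abs(evaluate_constraints(asm$state, asm$joints))), 0)
})

test_that("degrees of freedom follow 6N minus the constraint rows", {
  # single free body
  free1 <- quiet_build(2, anchor = "none", bead = FALSE)
  free1$joints <- free1$joints[0, ]
  expect_equal(count_dof(free1), 12)
  # free chain: 6N - 3(N-1) = 3N + 3
  for (n in c(5, 12, 50)) {
    asm <- quiet_build(n, anchor = "none", bead = FALSE)
    expect_equal(count_dof(asm), 3 * n + 3)
  }
  # anchored chain of 4 bodies with 4 ball joints: enumeration gives 12
  asm4 <- fixture_chain4()
  expect_equal(count_dof(asm4), 6 * 4 - 3 * 4)
  # weld anchor and bead add their rows; clamps add theirs
  asmb <- quiet_build(4, anchor = "weld", bead = TRUE, bead_radius_nm = 10)
  expect_equal(count_dof(asmb), 6 * 5 - (6 + 3 * 3 + 6))
  expect_equal(count_dof(asmb, "turn"), count_dof(asmb) - 3)
  expect_equal(count_dof(asmb, "torque"), count_dof(asmb) - 2)
})

test_that("the Boltzmann configuration sampler matches its target laws", {
  # FJC under tension: mean relative extension = L(x)
  a <- quiet_build(40, anchor = "ball", bead = FALSE, g_b = 0, g_t = 0)
  z <- vapply(1:400, function(k) {
    s <- sample_chain_configuration(a, force = 2, seed = k)
    st <- s$state
    (st$pos[40, ] + quat_rotate(st$quat[40, ], c(0, 0, 0.5)))[3]
  }, 1.0)
  expect_equal(mean(z) / 40, langevin_function(2),
               tolerance = 3 * stats::sd(z) / sqrt(400) / 40 /
                 langevin_function(2) + 0.01)
  # joints exactly closed after resampling
  s <- sample_chain_configuration(a, force = 2, seed = 1)
  expect_lt(max(abs(evaluate_constraints(s$state, s$joints))), 1e-12)
  # WLC at zero force: per-joint <t_i . t_i+1> = L(g_b)
  b <- quiet_build(30, anchor = "none", bead = FALSE)
  ct <- unlist(lapply(1:200, function(k) {
    s <- sample_chain_configuration(b, seed = k)
    tg <- t(vapply(seq_len(30), function(i)
      quat_rotate(s$state$quat[i, ], c(0, 0, 1)), rep(0, 3)))
    rowSums(tg[-30, ] * tg[-1, ])
  }))
  expect_equal(mean(ct), langevin_function(b$elastic$g_b),
               tolerance = 0.01)
  expect_error(sample_chain_configuration(b, force = 1), "zero force")
})

test_that("force-extension approaches full extension at large force", {
  asm <- quiet_build(16, anchor = "ball", bead = FALSE, g_b = 0, g_t = 0)
  fe <- run_force_extension(asm, forces_reduced = c(3, 10, 30),
                            equil_steps = 2e4, sample_steps = 1.2e5,
                            thermostat = thermostat_params("local"),
                            seed = 3, collisions = FALSE,
                            init_boltzmann = TRUE)
  expect_true(all(diff(fe$rel_ext) > 0))
  expect_true(all(fe$rel_ext < 1))
  expect_gt(fe$rel_ext[3], 0.9)
  expect_true(all(c("force_pN", "x", "z_mean", "z_se", "rel_ext") %in%
                    names(fe)))
  expect_s3_class(fe, "fe_curve")
})

test_that("turn clamp at n = 0 reproduces the force-extension point", {
  asm <- quiet_build(12, anchor = "weld", bead = TRUE, bead_radius_nm = 10,
                     salt_mM = 100)
  set.seed(1)
  hat0 <- run_turn_clamp(asm, force_reduced = 1, turns = 0,
                         equil_steps = 4e4, sample_steps = 1.5e5,
                         seed = 11, obs_stride = 100, wr_stride = 20)
  fe <- run_force_extension(asm, forces_reduced = 1,
                            equil_steps = 4e4, sample_steps = 1.5e5, seed = 12)
  # the clamp locks the bead tilt, which force-extension leaves free, so
  # allow a small systematic offset on top of the statistical bound
  expect_lt(abs(hat0$z_mean - fe$z_mean),
            3 * sqrt(hat0$z_se^2 + fe$z_se^2) + 0.005 * asm$L0)
  expect_equal(hat0$sigma, 0)
  expect_s3_class(hat0, "hat_curve")
})

test_that("torque clamp at zero torque stays at zero overtwist", {
  asm <- quiet_build(12, anchor = "weld", bead = TRUE, bead_radius_nm = 10)
  tc <- run_torque_clamp(asm, force_reduced = 1, torques_kBT = 0,
                         equil_steps = 3e4, sample_steps = 1.5e5, seed = 21)
  expect_lt(abs(tc$sigma_mean), 3 * tc$sigma_se + 0.01)
  expect_s3_class(tc, "torque_curve")
})

test_that("protocol guards reject inconsistent assemblies", {
  free <- fixture_free_chain(5)
  expect_error(run_turn_clamp(free, force_reduced = 1, turns = 1),
               "bead")
  expect_error(run_torque_clamp(free, force_reduced = 1, torques_kBT = 1),
               "bead")
  asm <- quiet_build(8, anchor = "weld", bead = TRUE, bead_radius_nm = 10)
  expect_error(run_simulation(asm, 10, clamp = "turn", turns = 5,
                              ramp_rate = 1e7), "ramp rate")
})
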