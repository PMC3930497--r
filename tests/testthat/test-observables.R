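# Measurement and reference-curve computations.

test_that("kinetic-energy statistics recognise the Gamma law", {
  set.seed(21)
  ndof <- 60
  e <- stats::rgamma(5000, shape = ndof / 2, scale = 1)
  ks <- kinetic_energy_stats(e, n_dof = ndof)
  expect_equal(ks$mean_ratio, 1, tolerance = 0.02)
  expect_gt(ks$ks_p, 0.01)
  # sensitivity control: wrong dof by 3 fails the mean test
  ks_bad <- kinetic_energy_stats(e, n_dof = ndof + 3)
  expect_gt(abs(ks_bad$mean_ratio - 1), 3 * ks_bad$mean_se_ratio)
  expect_error(kinetic_energy_stats(e[1:50], 10), "short")
})

test_that("autocorrelation handles constant, white and OU series", {
  const <- autocorrelation(rep(2, 500), max_lag = 20)
  expect_true(all(const$c == 1))
  expect_true(all(const$comp == 0))
  set.seed(2)
  wn <- autocorrelation(rnorm(20000), max_lag = 10)
  expect_lt(max(abs(wn$c[-1])), 3 / sqrt(20000))
  # OU with known relaxation time
  x <- ou_series(2e5, tau = 25, dt = 1, seed = 5)
  ac <- autocorrelation(x, max_lag = 150)
  fit <- fit_relaxation_time(ac)
  expect_equal(fit$tau, 25, tolerance = 0.1)
  expect_s3_class(fit, "relax_fit")
  expect_true(all(c("term", "estimate") %in% names(tidy(fit))))
  expect_warning(autocorrelation(c(rep(0, 200), rep(6, 200))),
                 "non-stationary")
})

test_that("tangent correlation recovers the calibrated persistence length", {
  # rigid rod: correlation identically one
  tg_rod <- array(0, c(5, 12, 3)); tg_rod[, , 3] <- 1
  tc_rod <- tangent_correlation(tg_rod)
  expect_true(all(tc_rod$corr == 1))
  expect_equal(tc_rod$corr[1], 1)   # s = 0
  # synthetic frames from the discrete WLC Boltzmann measure
  g_b <- calibrate_rigidity(50, 3.4)   # l_p = 14.7 b
  tg <- wlc_tangent_draw(400, 60, g_b, seed = 8)
  tc <- tangent_correlation(tg, max_s = 40)
  fit <- fit_persistence_length(tc, b = 1, fit_floor = 0.3)
  expect_equal(fit$l_p, 50 / 3.4, tolerance = 0.05)
  expect_s3_class(fit, "persistence_fit")
  expect_equal(glance(fit)$l_p, fit$l_p)
})

test_that("writhe agrees with independent quadrature and planar curves vanish", {
  # planar zig-zag: writhe 0
  set.seed(3)
  planar <- cbind(cumsum(runif(8)), cumsum(rnorm(8)), 0)
  expect_equal(rbdna:::cpp_polyline_writhe(planar), 0, tolerance = 1e-12)
  for (k in 1:5) {
    pts <- matrix(cumsum(rnorm(24, sd = 1)), ncol = 3)
    expect_equal(rbdna:::cpp_polyline_writhe(pts), writhe_quadrature(pts),
                 tolerance = 1e-6)
  }
  # a (closed-up) helix carries writhe close to n_turns * (1 - sin(alpha))
  th <- seq(0, 6 * pi, length.out = 200)
  R <- 1; pitch <- 0.3
  helix <- cbind(R * cos(th), R * sin(th), pitch * th / (2 * pi))
  # close it far away
  H <- 500
  closed <- rbind(c(helix[1, 1:2], -H), helix,
                  c(helix[200, 1:2], H + helix[200, 3]))
  alpha <- atan2(pitch, 2 * pi * R)
  expect_equal(rbdna:::cpp_polyline_writhe(closed), 3 * (1 - sin(alpha)),
               tolerance = 0.05)
})

test_that("twist/writhe bookkeeping and overtwist arithmetic", {
  asm <- quiet_build(10, anchor = "weld", bead = TRUE, bead_radius_nm = 10)
  tw <- twist_writhe(asm)
  expect_equal(tw$Tw, 0)
  expect_equal(tw$Wr, 0, tolerance = 1e-6)   # straight vertical chain
  expect_equal(overtwist(15, 300), 0.05)
  expect_error(chain_polyline(asm, closure = FALSE), "closure")
})

test_that("FJC and WLC reference curves evaluate correctly", {
  expect_equal(fjc_extension(3), 1 / tanh(3) - 1 / 3)
  expect_lt(abs(fjc_extension(3) - 0.6716), 5e-4)
  expect_equal(fjc_extension(0), 0)
  # WLC low-force limit: f ~ (3 kBT / 2 l_p) z for small z
  lp <- 14.7
  for (z in c(0.02, 0.05, 0.1)) {
    expect_equal(wlc_interpolation_force(z, lp), 1.5 * z / lp,
                 tolerance = 0.05)
  }
  # divergence near full extension and domain error beyond
  expect_gt(wlc_interpolation_force(0.99, lp), 100 / lp)
  expect_error(wlc_interpolation_force(1, lp), "extension")
})

test_that("hat-curve slope extraction finds the plectonemic linear region", {
  # noiseless synthetic: plateau then a line with slope -0.8
  n <- 0:12
  z <- ifelse(n <= 4, 10, 10 - 0.8 * (n - 4))
  fit <- hat_curve_slope(data.frame(n = n, z_mean = z), min_points = 3)
  expect_equal(fit$q, -0.8, tolerance = 1e-10)
  expect_s3_class(fit, "hat_fit")
  expect_equal(glance(fit)$q, fit$q)
  # symmetric negative branch
  d2 <- data.frame(n = -n, z_mean = z)
  fit2 <- hat_curve_slope(d2, branch = "negative")
  expect_equal(abs(fit2$q), 0.8, tolerance = 1e-10)
  # flat curve: no linear region
  expect_error(hat_curve_slope(data.frame(n = 0:8, z_mean = rep(5, 9))),
               "linear region")
})

test_that("supercoil relation round-trips through its inversion", {
  for (k in 1:20) {
    set.seed(k)
    R <- runif(1, 0.5, 4); alpha <- runif(1, 0.2, 1.2); f <- runif(1, 0.3, 4)
    q <- supercoil_relation(R, alpha, ratio = 1.9, f = f)
    expect_lt(q, 0)
    inv <- invert_supercoil_relation(q, alpha, ratio = 1.9, f = f)
    expect_equal(inv$R, R, tolerance = 1e-6)
  }
})

test_that("plectoneme geometry estimator sees an ideal superhelix", {
  # construct a two-start interwound superhelix of capsules by hand
  ns <- 30; Rsh <- 1.2; alpha <- 0.9
  # strand tangents make angle alpha with the superhelix axis (z)
  dz <- sin(alpha)
  dth <- cos(alpha) / Rsh
  n <- 2 * ns
  asm <- quiet_build(n, anchor = "none", bead = FALSE, salt_mM = 100)
  st <- asm$state
  th <- 0; z <- 0
  place <- function(i, th, z, up, phase) {
    p0 <- c(Rsh * cos(th + phase), Rsh * sin(th + phase), z)
    tang <- c(-Rsh * sin(th + phase) * dth, Rsh * cos(th + phase) * dth,
              if (up) dz else dz) # both strands run upward here
    tang <- tang / sqrt(sum(tang^2))
    list(p = p0, t = tang)
  }
  for (i in seq_len(ns)) {
    a <- place(i, th, z, TRUE, 0)
    b <- place(i, th, z, TRUE, pi)
    st$pos[i, ] <- a$p + a$t / 2
    st$pos[ns + i, ] <- b$p + b$t / 2
    # orientation: rotate z-axis onto the tangent
    for (j in c(i, ns + i)) {
      tg <- if (j <= ns) a$t else b$t
      ax <- cross3(c(0, 0, 1), tg)
      ang <- acos(max(-1, min(1, tg[3])))
      st$quat[j, ] <- if (sqrt(sum(ax^2)) < 1e-12) c(1, 0, 0, 0) else
        quat_from_axis_angle(ax, ang)
    }
    th <- th + dth; z <- z + dz
  }
  asm$state <- st
  geo <- estimate_plectoneme_geometry(asm, min_separation = 4, slack = 2.2)
  expect_gt(geo$n_pairs, 5)
  expect_equal(geo$R, Rsh, tolerance = 0.25)
  expect_equal(geo$alpha, alpha, tolerance = 0.25)
})

test_that("buckling analysis recovers telegraph dwell statistics", {
  tg <- telegraph_series(20000, p_up = 0.3, rate = 0.01, lo = 2, hi = 6,
                         noise = 0.3, seed = 4)
  sigma <- ifelse(tg$state, 0.02, 0.06) + rnorm(20000, sd = 0.005)
  ba <- buckling_analysis(tg$series, sigma)
  expect_equal(ba$dwell_high, mean(tg$state), tolerance = 0.05)
  expect_equal(ba$z_low, 2, tolerance = 0.2)
  expect_equal(ba$z_high, 6, tolerance = 0.2)
  expect_gt(ba$bimodality, 0)
  expect_lt(ba$cor_z_sigma, 0)    # constructed anticorrelation
})

test_that("critical torque sits at the overtwist-variance peak", {
  sweep <- tibble::tibble(torque = seq(2, 8, by = 1),
                          sigma_var = c(1, 2, 5, 9, 6, 2, 1) * 1e-5)
  ct <- estimate_critical_torque(sweep)
  expect_equal(ct$gamma_c, 5, tolerance = 0.5)
  expect_true(ct$peak_interior)
  expect_warning(
    estimate_critical_torque(tibble::tibble(torque = 1:4,
                                            sigma_var = c(4, 3, 2, 1) * 1e-5)),
    "edge")
})

test_that("affine torque law fit is exact on synthetic data", {
  xi_p <- 15; sigma_star <- 0.012; pitch <- 1
  sig <- seq(0.02, 0.08, by = 0.005)
  gam <- 2 * pi * xi_p / pitch * (sig - sigma_star)
  fit <- fit_affine_torque_law(data.frame(sigma = sig, torque = gam),
                               pitch = pitch)
  expect_equal(fit$xi_p, xi_p, tolerance = 1e-10)
  expect_equal(fit$sigma_star, sigma_star, tolerance = 1e-10)
  expect_equal(tidy(fit)$estimate, c(xi_p, sigma_star), tolerance = 1e-9)
  expect_error(fit_affine_torque_law(data.frame(sigma = sig, torque = -gam)),
               "positive")
})

test_that("batch statistics flag drifting series", {
  set.seed(11)
  flat <- batch_stats(rnorm(4000))
  expect_false(flat$drift)
  expect_equal(flat$mean, 0, tolerance = 0.06)
  drifting <- batch_stats(rnorm(4000) + seq(0, 3, length.out = 4000))
  expect_true(drifting$drift)
})
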