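# Capsule/plane/sphere narrow phase, broad phase and contact rows.

two_capsules <- function(pos2, quat2 = c(1, 0, 0, 0), radius = 1) {
  shape <- tibble::tibble(type = c("capsule", "capsule"), radius = radius,
                          length = 1)
  inertia <- matrix(rep(suppressMessages(capsule_inertia(1, radius, 1)),
                        each = 2), 2, 3)
  chain_state(rbind(c(0, 0, 0), pos2),
              rbind(c(1, 0, 0, 0), quat2),
              mass = c(1, 1), inertia = inertia, shape = shape)
}

test_that("capsule-capsule contact geometry is exact for parallel capsules", {
  # axes 1.8 apart, radius 1 each: depth = 2 - 1.8 = 0.2
  st <- two_capsules(c(1.8, 0, 0))
  ct <- capsule_capsule_contact(st, 1, 2)
  expect_equal(ct$depth, 0.2)
  expect_equal(ct$normal, c(-1, 0, 0))   # from body 2 toward body 1
  # contact point midway between the axes (its height along the parallel
  # overlap is degenerate and implementation-defined)
  expect_equal(ct$point[1], 0.9)
  expect_equal(ct$point[2], 0)
  # axes 2.5 apart: no contact
  expect_null(capsule_capsule_contact(two_capsules(c(2.5, 0, 0)), 1, 2))
  # coincident axes: deterministic fallback with a warning
  expect_warning(ct0 <- capsule_capsule_contact(two_capsules(c(0, 0, 0)), 1, 2),
                 "fallback")
  expect_equal(sqrt(sum(ct0$normal^2)), 1)
})

test_that("segment-segment distance matches brute-force minimization", {
  set.seed(13)
  for (k in 1:60) {
    p1 <- rnorm(3); q1 <- p1 + rnorm(3)
    p2 <- rnorm(3); q2 <- p2 + rnorm(3)
    d_impl <- segment_closest_points(p1, q1, p2, q2)$d
    d_cpp <- rbdna:::cpp_segseg(p1, q1, p2, q2)$d
    d_oracle <- segdist_bruteforce(p1, q1, p2, q2)
    expect_equal(d_impl, d_oracle, tolerance = 1e-6)
    expect_equal(d_cpp, d_oracle, tolerance = 1e-6)
  }
})

test_that("plane and sphere contacts report correct depth and normal", {
  # horizontal capsule, centre at z = r - 0.05
  r <- 0.4
  shape <- tibble::tibble(type = "capsule", radius = r, length = 1)
  st <- chain_state(matrix(c(0, 0, r - 0.05), 1),
                    matrix(quat_from_axis_angle(c(0, 1, 0), pi / 2), 1),
                    mass = 1,
                    inertia = matrix(suppressMessages(capsule_inertia(1, r, 1)), 1),
                    shape = shape)
  ct <- capsule_plane_contact(st, 1)
  expect_equal(ct$depth, 0.05, tolerance = 1e-12)
  expect_equal(ct$normal, c(0, 0, 1))
  # fully above the plane
  st$pos[1, 3] <- r + 0.01
  expect_null(capsule_plane_contact(st, 1))
  # capsule vs sphere: vertical capsule at origin, sphere on the x axis
  shape2 <- tibble::tibble(type = c("capsule", "sphere"),
                           radius = c(0.4, 1), length = c(1, 2))
  st2 <- chain_state(rbind(c(0, 0, 0), c(1.2, 0, 0)),
                     rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                     mass = c(1, 1),
                     inertia = rbind(suppressMessages(capsule_inertia(1, 0.4, 1)),
                                     rep(0.4, 3)),
                     shape = shape2)
  ct2 <- capsule_sphere_contact(st2, 1, 2)
  expect_equal(ct2$depth, 0.4 + 1 - 1.2, tolerance = 1e-12)
  expect_equal(ct2$normal, c(-1, 0, 0))
  # random placements vs brute force through the point-segment distance
  set.seed(4)
  for (k in 1:50) {
    st2$pos[2, ] <- rnorm(3)
    a <- capsule_axis(st2, 1)
    d <- segdist_bruteforce(a$p, a$q, st2$pos[2, ], st2$pos[2, ])
    ct3 <- capsule_sphere_contact(st2, 1, 2)
    if (d >= 1.4) expect_null(ct3) else {
      expect_equal(ct3$depth, 1.4 - d, tolerance = 1e-6)
    }
  }
})

test_that("broad phase returns a superset of the exhaustive pair check", {
  # straight dilute chain: nothing
  asm <- quiet_build(12, anchor = "none", bead = FALSE, salt_mM = 100)
  win <- bonded_exclusion_window(asm$radius)
  excl <- do.call(rbind, lapply(seq_len(win), function(w)
    cbind(seq_len(12 - w), seq_len(12 - w) + w)))
  prs <- broad_phase(asm$state, cutoff = 1 + 2 * asm$radius, exclude = excl)
  ok <- apply(prs, 1, function(p) {
    a1 <- capsule_axis(asm$state, p[1]); a2 <- capsule_axis(asm$state, p[2])
    segdist_bruteforce(a1$p, a1$q, a2$p, a2$q) < 2 * asm$radius
  })
  expect_false(any(ok))   # straight chain: no non-bonded overlaps
  # hairpin: the touching arm pair must be reported
  hp <- quiet_hairpin(4)
  win <- bonded_exclusion_window(hp$radius)
  excl <- do.call(rbind, lapply(seq_len(win), function(w)
    cbind(seq_len(hp$n_cylinders - w), seq_len(hp$n_cylinders - w) + w)))
  prs_hp <- broad_phase(hp$state, cutoff = 1 + 2 * hp$radius, exclude = excl)
  touching <- apply(prs_hp, 1, function(p) {
    a1 <- capsule_axis(hp$state, p[1]); a2 <- capsule_axis(hp$state, p[2])
    segdist_bruteforce(a1$p, a1$q, a2$p, a2$q) < 2 * hp$radius
  })
  expect_gt(sum(touching), 0)
  # random configurations: broad phase superset of the exhaustive O(N^2)
  # pair check (distances via the separately validated narrow phase)
  for (seed in 1:25) {
    st <- random_state(12, 400 + seed, radius = 0.45)
    st$pos <- st$pos * 1.5
    prs <- broad_phase(st, cutoff = 1 + 0.9)
    key <- paste(prs[, 1], prs[, 2])
    for (i in 1:11) for (j in (i + 1):12) {
      if (j - i <= 1) next
      ai <- capsule_axis(st, i); aj <- capsule_axis(st, j)
      if (segment_closest_points(ai$p, ai$q, aj$p, aj$q)$d < 0.9) {
        expect_true(paste(i, j) %in% key)
      }
    }
  }
})

test_that("hairpin fixture produces contacts on the first collision pass", {
  hp <- quiet_hairpin()
  cts <- detect_contacts(hp$state, plane = FALSE)
  expect_gt(length(cts), 0)
  expect_true(all(vapply(cts, function(ct) ct$depth, 1.0) > 0))
  expect_true(all(vapply(cts, function(ct)
    abs(sqrt(sum(ct$normal^2)) - 1), 1.0) < 1e-9))
  # bonded neighbours never appear
  prs <- t(vapply(cts, function(ct) c(ct$body_1, ct$body_2), c(1, 1)))
  expect_true(all(abs(prs[, 1] - prs[, 2]) >
                    bonded_exclusion_window(hp$radius)))
})

test_that("contact rows push overlapping bodies apart, never pull", {
  st <- two_capsules(c(1.8, 0, 0), radius = 1)
  ct <- capsule_capsule_contact(st, 1, 2)
  joints <- joint_table(character(0), integer(0), integer(0),
                        matrix(0, 0, 3), matrix(0, 0, 3))
  dt <- 0.000592
  # approaching bodies -> positive lambda, post-step separation velocity
  st$vel[1, ] <- c(0.5, 0, 0); st$vel[2, ] <- c(-0.5, 0, 0)
  st1 <- step_state(st, rep(0, 12), joints, dt, solver_params(),
                    contacts = list(ct))
  v_n <- sum((st1$vel[1, ] - st1$vel[2, ]) * ct$normal)
  expect_gte(v_n, 0)          # no longer approaching
  # separating bodies with zero depth -> lambda = 0 (complementarity):
  # velocities unchanged
  st$vel[1, ] <- c(-0.3, 0, 0); st$vel[2, ] <- c(0.3, 0, 0)
  ct0 <- ct; ct0$depth <- 0
  st2 <- step_state(st, rep(0, 12), joints, dt, solver_params(),
                    contacts = list(ct0))
  expect_equal(st2$vel, st$vel, tolerance = 1e-12)
  # resting contact at zero depth and zero velocity: nothing happens
  st$vel[] <- 0
  st3 <- step_state(st, rep(0, 12), joints, dt, solver_params(),
                    contacts = list(ct0))
  expect_equal(st3$vel, st$vel)
})

test_that("collision handling switches off cleanly for non-touching chains", {
  asm <- thermal_velocities(quiet_build(8, anchor = "none", bead = FALSE),
                            seed = 3)
  r1 <- run_simulation(asm, 500, thermostat = thermostat_params("off"),
                       seed = 1, collisions = TRUE, obs_stride = 100,
                       wr_stride = 0)
  r2 <- run_simulation(asm, 500, thermostat = thermostat_params("off"),
                       seed = 1, collisions = FALSE, obs_stride = 100,
                       wr_stride = 0)
  expect_identical(r1$assembly$state$pos, r2$assembly$state$pos)
  expect_identical(r1$assembly$state$quat, r2$assembly$state$quat)
})
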