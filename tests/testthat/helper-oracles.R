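# Independent oracles used across the test files. Each deliberately takes a
# different computational route from the implementation it checks.

# rotation matrix via Rodrigues' formula from the axis-angle of q
# (independent of quat_to_matrix's product formula)
rotmat_rodrigues <- function(q) {
  q <- q / sqrt(sum(q^2))
  ang <- 2 * acos(max(-1, min(1, q[1])))
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-14) return(diag(3))
  a <- v / s
  K <- skew3(a)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# cylinder inertia by midpoint quadrature over (radius, height)
inertia_quadrature <- function(mass, radius, length, nr = 600, nz = 600) {
  r <- (seq_len(nr) - 0.5) / nr * radius
  z <- (seq_len(nz) - 0.5) / nz * length - length / 2
  wr <- r                      # area weight ~ r dr
  wr <- wr / sum(wr) / nz      # normalize total mass to 1 (times nz cells)
  W <- outer(wr, rep(1, nz))
  i_axis <- mass * sum(W * outer(r^2, rep(1, nz)))
  i_perp <- mass * sum(W * (outer(r^2 / 2, rep(1, nz)) +
                              outer(rep(1, nr), z^2)))
  c(i_perp, i_perp, i_axis)
}

# random valid rigid-body chain state (not necessarily assembled)
random_state <- function(n, seed, radius = 0.4) {
  set.seed(seed)
  pos <- matrix(rnorm(3 * n, sd = 2), n, 3)
  quat <- matrix(rnorm(4 * n), n, 4)
  quat <- quat / sqrt(rowSums(quat^2))
  vel <- matrix(rnorm(3 * n), n, 3)
  angvel <- matrix(rnorm(3 * n), n, 3)
  shape <- tibble::tibble(type = rep("capsule", n), radius = radius,
                          length = 1)
  inertia <- matrix(rep(suppressMessages(capsule_inertia(1, radius, 1)),
                        each = n), n, 3)
  chain_state(pos, quat, vel, angvel, mass = rep(1, n), inertia = inertia,
              shape = shape)
}

# serial anchored chain with slightly perturbed geometry and random motion
random_perturbed_chain <- function(n, seed, anchor = TRUE, eps = 1e-3) {
  set.seed(seed)
  asm <- suppressMessages(suppressWarnings(
    build_assembly(n, anchor = if (anchor) "ball" else "none", bead = FALSE,
                   salt_mM = 100)))
  st <- asm$state
  st$pos <- st$pos + matrix(rnorm(3 * n, sd = eps), n, 3)
  dq <- matrix(rnorm(4 * n, sd = eps), n, 4)
  st$quat <- st$quat + dq
  st$quat <- st$quat / sqrt(rowSums(st$quat^2))
  st$vel <- matrix(rnorm(3 * n), n, 3)
  st$angvel <- matrix(rnorm(3 * n), n, 3)
  asm$state <- st
  asm
}

# brute-force segment-segment distance: coarse grid + alternating exact
# 1-D minimization (coordinate descent on a biconvex quadratic)
segdist_bruteforce <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2
  f <- function(s, t) sum(((p1 + s * d1) - (p2 + t * d2))^2)
  gr <- seq(0, 1, length.out = 41)
  vals <- outer(gr, gr, Vectorize(f))
  ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  s <- gr[ix[1]]; t <- gr[ix[2]]
  a <- sum(d1 * d1); e <- sum(d2 * d2); b <- sum(d1 * d2)
  for (it in 1:200) {
    r <- p1 - p2
    s_new <- if (a > 0) min(max((b * t - sum(d1 * r)) / a, 0), 1) else 0
    t_new <- if (e > 0) min(max((b * s_new + sum(d2 * r)) / e, 0), 1) else 0
    if (abs(s_new - s) < 1e-15 && abs(t_new - t) < 1e-15) break
    s <- s_new; t <- t_new
  }
  sqrt(f(s, t))
}

# exhaustive active-set enumeration for the mixed LCP with lower bounds 0
# on the bounded rows (<= 12 bounded rows)
lcp_enumeration <- function(A, rhs, bounded) {
  m <- length(rhs)
  nb <- length(bounded)
  for (mask in 0:(2^nb - 1)) {
    clamped <- bounded[bitwAnd(mask, 2^(seq_len(nb) - 1)) > 0]
    free <- setdiff(seq_len(m), clamped)
    lam <- numeric(m)
    if (length(free)) {
      lam[free] <- solve(A[free, free, drop = FALSE], rhs[free])
    }
    resid <- as.numeric(A %*% lam - rhs)
    ok_free <- all(lam[intersect(free, bounded)] >= -1e-9)
    ok_clamped <- all(resid[clamped] >= -1e-9)
    if (ok_free && ok_clamped) return(lam)
  }
  stop("lcp_enumeration: no consistent active set found")
}

# discrete OU process with known relaxation time
ou_series <- function(n, tau, dt, sigma = 1, seed = 1) {
  set.seed(seed)
  a <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sigma)
  innov <- rnorm(n - 1, sd = sigma * sqrt(1 - a^2))
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i - 1]
  x
}

# two-state telegraph process plus Gaussian noise
telegraph_series <- function(n, p_up = 0.3, rate = 0.01, lo = 0, hi = 1,
                             noise = 0.05, seed = 1) {
  set.seed(seed)
  state <- logical(n)
  state[1] <- runif(1) < p_up
  # asymmetric rates giving stationary P(up) = p_up
  p01 <- rate                      # down -> up
  p10 <- rate * (1 - p_up) / p_up  # up -> down
  for (i in 2:n) {
    state[i] <- if (state[i - 1]) runif(1) > p10 else runif(1) < p01
  }
  list(state = state,
       series = ifelse(state, hi, lo) + rnorm(n, sd = noise))
}

# tangent array drawn directly from the discrete worm-like-chain Boltzmann
# measure (independent route from the simulator)
wlc_tangent_draw <- function(n_chains, n_seg, g_b, seed = 1) {
  set.seed(seed)
  tg <- array(0, c(n_chains, n_seg, 3))
  for (ch in seq_len(n_chains)) {
    t_cur <- c(0, 0, 1)
    for (i in seq_len(n_seg)) {
      if (i > 1) {
        ct <- 1 + log(runif(1) * (1 - exp(-2 * g_b)) + exp(-2 * g_b)) / g_b
        ct <- max(-1, min(1, ct))
        ph <- runif(1, 0, 2 * pi)
        # rotate t_cur by acos(ct) about a random perpendicular axis
        perp <- c(-t_cur[2], t_cur[1], 0)
        if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
        perp <- perp / sqrt(sum(perp^2))
        axis <- quat_rotate(quat_from_axis_angle(t_cur, ph), perp)
        st <- sqrt(1 - ct^2)
        t_cur <- ct * t_cur + st * cross3(axis, t_cur)
        t_cur <- t_cur / sqrt(sum(t_cur^2))
      }
      tg[ch, i, ] <- t_cur
    }
  }
  tg
}

# writhe of a polyline by two-point Gauss-Legendre quadrature per segment
# pair (independent of the solid-angle formula in the engine)
writhe_quadrature <- function(pts, n_gauss = 24) {
  gl <- pracma::gaussLegendre(n_gauss, 0, 1)
  ns <- nrow(pts) - 1
  tot <- 0
  for (i in 1:(ns - 1)) {
    for (j in (i + 2):ns) {
      if (j > ns) next
      a <- pts[i, ]; b <- pts[i + 1, ]; cc <- pts[j, ]; d <- pts[j + 1, ]
      t1 <- b - a; t2 <- d - cc
      cr <- cross3(t1, t2)
      s <- 0
      for (u in seq_len(n_gauss)) {
        ru <- a + gl$x[u] * t1
        for (v in seq_len(n_gauss)) {
          r <- ru - (cc + gl$x[v] * t2)
          s <- s + gl$w[u] * gl$w[v] * sum(cr * r) / sum(r * r)^1.5
        }
      }
      tot <- tot + s
    }
  }
  tot / (2 * pi)
}

# quiet wrappers: the fat-capsule builds log a near-spherical note
quiet_build <- function(...) {
  suppressMessages(suppressWarnings(build_assembly(...)))
}
quiet_hairpin <- function(...) {
  suppressMessages(suppressWarnings(fixture_hairpin(...)))
}
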