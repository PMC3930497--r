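#' Batch-means standard error of a correlated series
#'
#' Splits a stationary series into `n_batches` contiguous batches and
#' estimates the standard error of the mean from the batch means,
#' compensating for autocorrelation as long as the batch length exceeds the
#' correlation time. Also runs a first-half/second-half drift test.
#'
#' @param x numeric series.
#' @param n_batches number of batches (default 20).
#' @return tibble with `mean`, `se`, `n_eff`, `drift` (logical: halves
#'   differ by more than 3 combined SE).
#' @export
batch_stats <- function(x, n_batches = 20) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2 * n_batches) n_batches <- max(2, floor(n / 2))
  bl <- floor(n / n_batches)
  bm <- vapply(seq_len(n_batches),
               function(b) mean(x[((b - 1) * bl + 1):(b * bl)]), 1.0)
  se <- stats::sd(bm) / sqrt(n_batches)
  h <- floor(n / 2)
  m1 <- mean(x[1:h]); m2 <- mean(x[(h + 1):n])
  drift <- is.finite(se) && se > 0 && abs(m1 - m2) > 3 * se * sqrt(2)
  tibble::tibble(mean = mean(x), se = se,
                 n_eff = n_batches, drift = drift)
}

#' Kinetic-energy statistics against the Boltzmann law
#'
#' At thermal equilibrium the kinetic energy of a system with `n_dof`
#' degrees of freedom has mean `n_dof kBT / 2` and is Gamma distributed
#' with shape `n_dof/2` and scale `kBT`. Returns the measured-to-expected
#' mean ratio and a Kolmogorov-Smirnov goodness-of-fit test of the series
#' against that Gamma density (thin the series to roughly independent
#' samples before testing).
#'
#' @param e_kin numeric series of kinetic energies.
#' @param n_dof degrees of freedom ([count_dof()]).
#' @param kBT thermal energy.
#' @return tibble with `mean_ratio`, `mean_se_ratio`, `ks_p`, `n`.
#' @export
kinetic_energy_stats <- function(e_kin, n_dof, kBT = 1) {
  e_kin <- e_kin[is.finite(e_kin)]
  if (length(e_kin) < 100) {
    stop("kinetic_energy_stats(): series too short (need >= 100 samples)",
         call. = FALSE)
  }
  expected <- n_dof * kBT / 2
  bs <- batch_stats(e_kin)
  ks <- suppressWarnings(
    stats::ks.test(e_kin, stats::pgamma, shape = n_dof / 2, scale = kBT))
  tibble::tibble(mean_ratio = bs$mean / expected,
                 mean_se_ratio = bs$se / expected,
                 ks_p = ks$p.value, n = length(e_kin))
}

#' Normalized autocorrelation function and relaxation time
#'
#' `autocorrelation()` returns the normalized autocovariance `c(lag)` of a
#' stationary series (`c(0) = 1`) together with the complementary function
#' `1 - c`; `fit_relaxation_time()` fits an exponential to the initial
#' decay (lags with `c` above `fit_floor`) and returns the relaxation time
#' with a confidence interval from the log-linear fit.
#'
#' @param x numeric series (regularly sampled).
#' @param max_lag maximum lag in samples.
#' @param dt_sample time between samples (for physical lag units).
#' @return tibble with `lag`, `t`, `c`, `comp`.
#' @export
autocorrelation <- function(x, max_lag = floor(length(x) / 4), dt_sample = 1) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) {
    return(tibble::tibble(lag = 0:max_lag, t = (0:max_lag) * dt_sample,
                          c = 1, comp = 0))
  }
  # drift check: halves differing by > 20% of sd suggests non-stationarity
  h <- floor(length(x) / 2)
  if (abs(mean(x[1:h]) - mean(x[-(1:h)])) > 0.5 * stats::sd(x)) {
    warning("autocorrelation(): series looks non-stationary")
  }
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = 0:max_lag, t = (0:max_lag) * dt_sample,
                 c = as.numeric(ac$acf), comp = 1 - as.numeric(ac$acf))
}

#' @rdname autocorrelation
#' @param ac a tibble from [autocorrelation()].
#' @param fit_floor smallest `c` included in the exponential fit.
#' @return `fit_relaxation_time()`: an object of class `relax_fit` with
#'   `tau`, `tau_lo`, `tau_hi` (95% CI) and the underlying `lm` fit.
#' @export
fit_relaxation_time <- function(ac, fit_floor = 0.2) {
  idx <- which(ac$c < fit_floor)
  last <- if (length(idx)) max(min(idx) - 1L, 3L) else nrow(ac)
  d <- ac[2:last, ]
  d <- d[d$c > 0, ]
  if (nrow(d) < 2) stop("fit_relaxation_time(): decay too fast to fit",
                        call. = FALSE)
  fit <- stats::lm(log(c) ~ t, data = d)
  sl <- stats::coef(fit)[["t"]]
  ci <- suppressMessages(stats::confint(fit))["t", ]
  if (sl >= 0) stop("fit_relaxation_time(): no decay detected", call. = FALSE)
  structure(list(tau = -1 / sl,
                 tau_lo = -1 / ci[[1]], tau_hi = -1 / max(ci[[2]], -Inf),
                 fit = fit, n_lags = nrow(d)),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("<relax_fit> tau = %.4g (95%% CI %.4g - %.4g), %d lags\n",
              x$tau, x$tau_lo, x$tau_hi, x$n_lags))
  invisible(x)
}

#' Tangent-tangent correlation and persistence-length fit
#'
#' `tangent_correlation()` averages `t_i . t_{i+s}` over chain positions
#' and trajectory frames; for a chain in equilibrium the decay is
#' `exp(-s b / l_p)` and `fit_persistence_length()` recovers `l_p` from a
#' log-linear fit.
#'
#' @param trajectory the `trajectory` element of a [run_simulation()]
#'   result (or an `n_frames x n x 3` tangent array).
#' @param max_s maximum contour separation (segments).
#' @return tibble with `s`, `corr`, `n_pairs`.
#' @export
tangent_correlation <- function(trajectory, max_s = NULL) {
  tg <- if (is.list(trajectory)) trajectory_tangents(trajectory) else trajectory
  n <- dim(tg)[2]
  if (is.null(max_s)) max_s <- n - 1
  max_s <- min(max_s, n - 1)
  corr <- numeric(max_s + 1)
  npairs <- integer(max_s + 1)
  for (s in 0:max_s) {
    i <- seq_len(n - s)
    prods <- tg[, i, 1, drop = FALSE] * tg[, i + s, 1, drop = FALSE] +
      tg[, i, 2, drop = FALSE] * tg[, i + s, 2, drop = FALSE] +
      tg[, i, 3, drop = FALSE] * tg[, i + s, 3, drop = FALSE]
    corr[s + 1] <- mean(prods)
    npairs[s + 1] <- length(prods)
  }
  tibble::tibble(s = 0:max_s, corr = corr, n_pairs = npairs)
}

#' @rdname tangent_correlation
#' @param tc tibble from [tangent_correlation()].
#' @param b segment length (reduced: 1).
#' @param fit_floor smallest correlation included in the fit.
#' @return `fit_persistence_length()`: object of class `persistence_fit`
#'   with `l_p` (same units as `b`) and the `lm` fit.
#' @export
fit_persistence_length <- function(tc, b = 1, fit_floor = 0.1) {
  d <- tc[tc$s > 0 & tc$corr > fit_floor, ]
  if (nrow(d) < 2) stop("fit_persistence_length(): not enough decaying points",
                        call. = FALSE)
  fit <- stats::lm(log(corr) ~ s, data = d)
  sl <- stats::coef(fit)[["s"]]
  if (sl >= 0) stop("fit_persistence_length(): correlation does not decay",
                    call. = FALSE)
  structure(list(l_p = -b / sl, b = b, fit = fit, n_points = nrow(d)),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("<persistence_fit> l_p = %.4g (x b = %g), %d points\n",
              x$l_p, x$b, x$n_points))
  invisible(x)
}

#' Twist, writhe and overtwist bookkeeping
#'
#' `twist_writhe()` returns the accumulated twist `Tw = sum(phi_i)/2pi`
#' (from the per-joint unwrapped twist angles carried by the assembly) and
#' the writhe `Wr` of the centreline, computed by the discrete Gauss double
#' sum over segment pairs with the open chain virtually closed by two
#' vertical rays (downward below the anchor, upward above the distal end).
#' For a turn-clamped molecule White's theorem gives
#' `n = (Tw - Tw0) + (Wr - Wr0)`.
#'
#' `overtwist()` converts turns to the relative overtwist
#' `sigma = n / Lk0`.
#'
#' @param assembly an assembly that has been advanced by
#'   [run_simulation()].
#' @return tibble with `Tw`, `Wr`.
#' @export
twist_writhe <- function(assembly) {
  tw <- sum(assembly$phi_cum) / (2 * pi)
  pts <- chain_polyline(assembly, closure = TRUE)
  tibble::tibble(Tw = tw, Wr = cpp_polyline_writhe(pts))
}

#' @rdname twist_writhe
#' @param closure add the two-ray virtual closure (required for a
#'   well-defined open-curve writhe; turning it off is an error unless the
#'   caller acknowledges a raw open-curve value).
#' @export
chain_polyline <- function(assembly, closure = TRUE) {
  st <- assembly$state
  n <- assembly$n_cylinders
  pts <- matrix(0, n + 1, 3)
  pts[1, ] <- st$pos[1, ] - quat_rotate(st$quat[1, ], c(0, 0, 0.5))
  for (i in seq_len(n)) {
    pts[i + 1, ] <- st$pos[i, ] + quat_rotate(st$quat[i, ], c(0, 0, 0.5))
  }
  if (!closure) {
    stop("chain_polyline(): open-curve writhe without the two-ray closure ",
         "is not defined; use closure = TRUE", call. = FALSE)
  }
  H <- 50 * n
  rbind(pts[1, ] - c(0, 0, H), pts, pts[n + 1, ] + c(0, 0, H))
}

#' @rdname twist_writhe
#' @param n number of bead turns (or cumulative bead angle / 2pi).
#' @param Lk0 relaxed linking number (chain length in helix pitches).
#' @export
overtwist <- function(n, Lk0) n / Lk0

#' @rdname wlc_interpolation_force
#' @param f stretching force (kBT per unit of `l_p`'s length unit times
#'   that unit; i.e. consistent units with `l_p`, `kBT`).
#' @return `wlc_extension()`: the relative extension at force `f`, by
#'   numerical inversion of the interpolation formula.
#' @export
wlc_extension <- function(f, l_p, kBT = 1) {
  vapply(f, function(ff) {
    stats::uniroot(function(z) wlc_interpolation_force(z, l_p, kBT) - ff,
                   lower = 1e-8, upper = 1 - 1e-8, tol = 1e-10)$root
  }, 1.0)
}

#' Freely-jointed-chain force-extension law
#'
#' `z/L0 = L(f b / kBT)` with `L` the Langevin function: the closed-form
#' response of a chain of rigid segments with free joints under tension.
#'
#' @param f stretching force (kBT/b units, or any units consistent with
#'   `b`, `kBT`).
#' @param b segment length.
#' @param kBT thermal energy.
#' @export
fjc_extension <- function(f, b = 1, kBT = 1) {
  langevin_function(f * b / kBT)
}

#' Worm-like-chain interpolation formula (force from relative extension)
#'
#' The seven-coefficient interpolation of the WLC force-extension relation
#' (Bouchiat et al. 1999), accurate to ~0.01% against the exact solution:
#' `f l_p / kBT = z + 1/(4(1-z)^2) - 1/4 + sum a_i z^i` with
#' `z` the relative extension.
#'
#' @param rel_ext relative extension `z/L0` in `[0, 1)`.
#' @param l_p persistence length.
#' @param kBT thermal energy.
#' @return force in units of `kBT / (unit of l_p)`.
#' @export
wlc_interpolation_force <- function(rel_ext, l_p, kBT = 1) {
  if (any(rel_ext >= 1)) {
    stop("wlc_interpolation_force(): relative extension must be < 1",
         call. = FALSE)
  }
  a <- c(-0.5164228, -2.737418, 16.07497, -38.87607, 39.49944, -14.17718)
  z <- rel_ext
  poly <- vapply(z, function(zz) sum(a * zz^(2:7)), 1.0)
  (kBT / l_p) * (z + 1 / (4 * (1 - z)^2) - 1 / 4 + poly)
}

#' Hat-curve slope in the plectonemic regime
#'
#' Fits the linear part of a rotation-extension ("hat") curve beyond the
#' buckling transition with a hinge (plateau-plus-line) model: for every
#' candidate buckling turn the points below it are modelled by their mean
#' and the points beyond by a straight line, and the breakpoint minimising
#' the total squared error wins. The slope of the winning line is the
#' plectonemic slope `q` (extension per turn, negative).
#'
#' @param curve data frame with turn and extension columns.
#' @param n_col,z_col column names.
#' @param branch `"positive"` or `"negative"` turns.
#' @param min_points minimum number of points in the linear region.
#' @return object of class `hat_fit` with `q` (extension per turn),
#'   `intercept`, `r2`, `window`, `n_buckling` and the `lm` fit.
#' @export
hat_curve_slope <- function(curve, n_col = "n", z_col = "z_mean",
                            branch = c("positive", "negative"),
                            min_points = 3) {
  branch <- match.arg(branch)
  d <- tibble::tibble(n = abs(curve[[n_col]]), z = curve[[z_col]],
                      n_signed = curve[[n_col]])
  d <- if (branch == "positive") d[d$n_signed >= 0, ] else d[d$n_signed <= 0, ]
  d <- d[order(d$n), ]
  if (nrow(d) < min_points + 1) {
    stop("hat_curve_slope(): too few points", call. = FALSE)
  }
  m <- nrow(d)
  best <- NULL
  for (k in 0:(m - min_points)) {       # k points in the plateau
    plateau <- if (k > 0) d$z[seq_len(k)] else numeric(0)
    lin <- d[(k + 1):m, ]
    fit <- stats::lm(z ~ n, data = lin)
    sse <- sum(stats::resid(fit)^2) +
      if (k > 0) sum((plateau - mean(plateau))^2) else 0
    sl <- stats::coef(fit)[["n"]]
    # the drop across the fitted window must be resolvable, not round-off
    resolvable <- -sl * diff(range(lin$n)) > 1e-6 * max(abs(d$z), 1)
    if (sl < 0 && resolvable && (is.null(best) || sse < best$sse)) {
      best <- list(fit = fit, k = k, sse = sse, sl = sl,
                   nb = if (k > 0) d$n[k] else 0)
    }
  }
  if (is.null(best)) {
    stop("hat_curve_slope(): no linear region detected beyond buckling",
         call. = FALSE)
  }
  r2 <- suppressWarnings(summary(best$fit)$r.squared)
  # q is the extension change per absolute turn (negative on both branches)
  q <- best$sl
  structure(list(q = q, intercept = stats::coef(best$fit)[[1]],
                 r2 = r2, window = m - best$k, n_buckling = best$nb,
                 branch = branch, fit = best$fit),
            class = "hat_fit")
}

#' @export
print.hat_fit <- function(x, ...) {
  cat(sprintf("<hat_fit> q = %.4g b/turn (%s branch, %d points, R^2 = %.3f)\n",
              x$q, x$branch, x$window, x$r2))
  invisible(x)
}

#' Plectoneme geometry relations
#'
#' `supercoil_relation()` predicts the linear hat-curve slope from the
#' superhelix radius `R` and angle `alpha`: each added turn converts a
#' length `4 pi R / sin(2 alpha)` of extended molecule (writhe density of a
#' two-start superhelix) into plectoneme, so the extension drops by that
#' length times the relative extension `rho(f)` of the extended state,
#' `q = -(4 pi R / sin 2 alpha) * rho(f)` with the WLC estimate
#' `rho = 1 - (1/2) sqrt(kBT / (f l_p))`. The twisting-to-bending ratio
#' `l_t/l_p` is accepted for interface compatibility and reported with the
#' result; the implemented relation does not use it.
#'
#' `invert_supercoil_relation()` recovers `(R, alpha)` exactly from the
#' pair (slope `q`, writhe density `wr_density = sin(2 alpha)/(4 pi R)`).
#'
#' @param R superhelix radius (b units).
#' @param alpha superhelical angle in (0, pi/2).
#' @param ratio twist-to-bend persistence ratio `l_t / l_p`.
#' @param f stretching force (kBT/b).
#' @param l_p bending persistence length (b units).
#' @param kBT thermal energy.
#' @export
supercoil_relation <- function(R, alpha, ratio, f, l_p = 50 / 3.4, kBT = 1) {
  stopifnot(R > 0, alpha > 0, alpha < pi / 2, f > 0)
  rho <- max(1 - 0.5 * sqrt(kBT / (f * l_p)), 0)
  -(4 * pi * R / sin(2 * alpha)) * rho
}

#' @rdname supercoil_relation
#' @param q hat-curve slope (b per turn, negative).
#' @param alpha_meas independently measured superhelical angle (e.g. from
#'   [estimate_plectoneme_geometry()]); the slope alone fixes only the
#'   combination `R / sin(2 alpha)`.
#' @export
invert_supercoil_relation <- function(q, alpha_meas, ratio, f,
                                      l_p = 50 / 3.4, kBT = 1) {
  stopifnot(q < 0, alpha_meas > 0, alpha_meas < pi / 2)
  rho <- max(1 - 0.5 * sqrt(kBT / (f * l_p)), 0)
  tibble::tibble(R = -q * sin(2 * alpha_meas) / (4 * pi * rho),
                 alpha = alpha_meas)
}

#' Estimate plectoneme geometry from a configuration
#'
#' Measures the superhelix radius as half the mean axis-to-axis distance of
#' contacting, contour-distant segment pairs, and the superhelical angle as
#' half the mean crossing angle of their tangents (the two strands of a
#' plectoneme cross at `pi - 2 alpha`). This contact-pair estimator is a
#' package construction; see the methods vignette for its limitations.
#'
#' @param assembly an assembly in a supercoiled configuration.
#' @param min_separation minimum contour separation (segments) for a pair
#'   to count as plectonemic.
#' @param slack distance slack (in radii) beyond touching.
#' @return tibble with `R`, `alpha`, `n_pairs`.
#' @export
estimate_plectoneme_geometry <- function(assembly, min_separation = 4,
                                         slack = 1.2) {
  st <- assembly$state
  n <- assembly$n_cylinders
  r <- assembly$radius
  dists <- c(); angs <- c()
  for (i in seq_len(n - min_separation)) {
    ai <- capsule_axis(st, i)
    for (j in seq(i + min_separation, n)) {
      if (abs(st$pos[i, 3] - st$pos[j, 3]) > 2 * slack * r + 1) next
      aj <- capsule_axis(st, j)
      cp <- segment_closest_points(ai$p, ai$q, aj$p, aj$q)
      if (cp$d < 2 * r * slack) {
        dists <- c(dists, cp$d)
        cang <- acos(min(1, abs(sum(ai$t * aj$t))))
        angs <- c(angs, (pi - cang) / 2)
      }
    }
  }
  if (!length(dists)) {
    return(tibble::tibble(R = NA_real_, alpha = NA_real_, n_pairs = 0L))
  }
  tibble::tibble(R = mean(dists) / 2, alpha = mean(angs),
                 n_pairs = length(dists))
}

#' Buckling and torque-law analysis
#'
#' `buckling_analysis()` decomposes extension/overtwist time series near
#' the buckling transition into two states (two-component Gaussian mixture
#' on the extension), reporting dwell fractions, state means, a bimodality
#' score (BIC preference of 2 components over 1) and the
#' extension-overtwist correlation (negative at buckling).
#'
#' `estimate_critical_torque()` locates the torque of maximal overtwist
#' variance in a torque sweep (the bistability criterion) by a quadratic
#' fit around the empirical peak.
#'
#' `fit_affine_torque_law()` fits the plectonemic-regime affine law
#' `Gamma = (2 pi kBT xi_p / p) (sigma - sigma_star)` returning the fitted
#' plectonemic twist length `xi_p` and offset overtwist `sigma_star`.
#'
#' @param z,sigma extension and overtwist series.
#' @return `buckling_analysis()`: tibble with `dwell_low`, `dwell_high`,
#'   `z_low`, `z_high`, `bimodality`, `cor_z_sigma`.
#' @export
buckling_analysis <- function(z, sigma) {
  z <- as.numeric(z); sigma <- as.numeric(sigma)
  ok <- is.finite(z) & is.finite(sigma)
  z <- z[ok]; sigma <- sigma[ok]
  fit2 <- Mclust(z, G = 2, modelNames = "V", verbose = FALSE)
  fit1 <- Mclust(z, G = 1, modelNames = "V", verbose = FALSE)
  cls <- fit2$classification
  mu <- fit2$parameters$mean
  lowc <- which.min(mu)
  tibble::tibble(
    dwell_low = mean(cls == lowc), dwell_high = mean(cls != lowc),
    z_low = min(mu), z_high = max(mu),
    bimodality = fit2$bic - fit1$bic,
    cor_z_sigma = suppressWarnings(stats::cor(z, sigma))
  )
}

#' @rdname buckling_analysis
#' @param sweep data frame with columns `torque` and `sigma_var`.
#' @export
estimate_critical_torque <- function(sweep) {
  d <- sweep[order(sweep$torque), ]
  if (nrow(d) < 3 || all(!is.finite(d$sigma_var))) {
    stop("estimate_critical_torque(): need a sweep with >= 3 torques",
         call. = FALSE)
  }
  k <- which.max(d$sigma_var)
  if (k == 1 || k == nrow(d)) {
    warning("variance peak at the edge of the sweep; critical torque ",
            "poorly determined")
    return(tibble::tibble(gamma_c = d$torque[k], gamma_c_se = NA_real_,
                          peak_interior = FALSE))
  }
  idx <- max(1, k - 1):min(nrow(d), k + 1)
  fit <- stats::lm(sigma_var ~ torque + I(torque^2), data = d[idx, ])
  cf <- stats::coef(fit)
  gc <- if (is.finite(cf[[3]]) && cf[[3]] < 0) -cf[[2]] / (2 * cf[[3]])
        else d$torque[k]
  tibble::tibble(gamma_c = gc,
                 gamma_c_se = abs(d$torque[k + 1] - d$torque[k - 1]) / 4,
                 peak_interior = TRUE)
}

#' @rdname buckling_analysis
#' @param df data frame with `sigma` and `torque` columns (plectonemic
#'   regime).
#' @param pitch helix pitch `p` in b units (1: one pitch per cylinder).
#' @param kBT thermal energy.
#' @return `fit_affine_torque_law()`: object of class `affine_fit` with
#'   `xi_p`, `sigma_star` and the `lm` fit.
#' @export
fit_affine_torque_law <- function(df, pitch = 1, kBT = 1) {
  fit <- stats::lm(torque ~ sigma, data = df)
  sl <- stats::coef(fit)[["sigma"]]
  if (sl <= 0) stop("fit_affine_torque_law(): slope must be positive in the ",
                    "plectonemic regime", call. = FALSE)
  structure(list(xi_p = sl * pitch / (2 * pi * kBT),
                 sigma_star = -stats::coef(fit)[[1]] / sl,
                 pitch = pitch, fit = fit),
            class = "affine_fit")
}

#' @export
print.affine_fit <- function(x, ...) {
  cat(sprintf("<affine_fit> xi_p = %.4g b, sigma* = %.4g\n",
              x$xi_p, x$sigma_star))
  invisible(x)
}
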