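#' Langevin function
#'
#' `L(x) = coth(x) - 1/x`, with a series branch near zero
#' (`x/3 - x^3/45 + O(x^5)`). Appears both in the rigidity calibration and
#' in the freely-jointed-chain force-extension law.
#'
#' @param x numeric.
#' @export
langevin_function <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Calibrate a rigidity constant from a persistence length
#'
#' The bending (or twisting) rigidity `g` of a discrete chain with segment
#' length `b` and an angular energy `g (1 - cos x)` per joint is related to
#' the corresponding persistence length `xi` through the Langevin-function
#' relation `L(g) = exp(-b / xi)`: averaging `cos` of the joint angle over
#' the Boltzmann distribution on the sphere gives exactly `L(g)`, and the
#' per-joint correlation decay must reproduce `exp(-b/xi)`. The relation is
#' monotone and solved by bracketed root-finding to 1e-10.
#'
#' With the standard DNA twisting persistence length of 95 nm and b = 3.4 nm
#' (10 bp) this yields a twisting rigidity of 28.4 kBT.
#'
#' @param persistence_length persistence length (same units as `b`).
#' @param b segment length.
#' @return rigidity constant in kBT units.
#' @seealso [rigidity_to_persistence()] for the inverse mapping.
#' @export
calibrate_rigidity <- function(persistence_length, b = 1) {
  if (persistence_length <= 0 || b <= 0) {
    stop("calibrate_rigidity(): lengths must be positive", call. = FALSE)
  }
  if (persistence_length < b / 10) {
    warning("persistence length below b/10: discretization too coarse for ",
            "this calibration to be meaningful")
  }
  target <- exp(-b / persistence_length)
  # L is monotone on (0, Inf) with range (0, 1); bracket then root-find
  # (L(g) ~ g/3 near zero, so g = target always lies below the root)
  lo <- min(1e-8, target)
  hi <- 4
  while (langevin_function(hi) < target) hi <- hi * 2
  stats::uniroot(function(g) langevin_function(g) - target,
                 lower = lo, upper = hi, tol = 1e-12)$root
}

#' @rdname calibrate_rigidity
#' @param g rigidity constant (kBT units).
#' @export
rigidity_to_persistence <- function(g, b = 1) {
  if (g <= 0 || b <= 0) stop("rigidity_to_persistence(): inputs must be positive",
                             call. = FALSE)
  -b / log(langevin_function(g))
}

#' Elastic parameters of the DNA chain
#'
#' Bundles the bending and twisting rigidities with their persistence
#' lengths and the segment length. Either persistence lengths (calibrated
#' through [calibrate_rigidity()]) or explicit rigidities may be given.
#'
#' @param l_p bending persistence length (length units; DNA: 50 nm).
#' @param l_t twisting persistence length (DNA: 95 nm).
#' @param b segment length (same units).
#' @param g_b,g_t explicit rigidity overrides in kBT (bypass calibration).
#' @return object of class `elastic_params`.
#' @export
elastic_params <- function(l_p = 50, l_t = 95, b = 3.4,
                           g_b = NULL, g_t = NULL) {
  gb <- if (is.null(g_b)) calibrate_rigidity(l_p, b) else g_b
  gt <- if (is.null(g_t)) {
    if (l_t <= 0) 0 else calibrate_rigidity(l_t, b)
  } else g_t
  if (!is.null(g_b)) l_p <- if (g_b > 0) rigidity_to_persistence(g_b, b) else 0
  if (!is.null(g_t)) l_t <- if (g_t > 0) rigidity_to_persistence(g_t, b) else 0
  structure(list(g_b = gb, g_t = gt, l_p = l_p, l_t = l_t, b = b),
            class = "elastic_params")
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf("<elastic_params> g_b = %.4g kBT (l_p = %.4g), g_t = %.4g kBT (l_t = %.4g), b = %g\n",
              x$g_b, x$l_p, x$g_t, x$l_t, x$b))
  invisible(x)
}

#' Bending and twisting angles between adjacent body frames
#'
#' Decomposes the relative rotation between the triads of two connected
#' cylinders in the ZXZ Euler convention with the tangent as the Z axis:
#' the bending angle `theta` (in `[0, pi]`) is the middle Euler angle, i.e.
#' the angle between the two tangents, and the twist `phi` is the sum of the
#' outer Euler angles, wrapped to `(-pi, pi]`. At the gimbal degeneracy
#' (antiparallel tangents) `phi` is indeterminate and is carried over from
#' `prev_phi` with a flag.
#'
#' @param frame_i,frame_i1 triads from [body_frame()] (columns `t`, `u`, `v`).
#' @param prev_phi twist to carry over at the gimbal singularity.
#' @return list with `theta`, `phi`, `gimbal` (logical).
#' @export
bend_twist_angles <- function(frame_i, frame_i1, prev_phi = NULL) {
  t1 <- frame_i[, 1]; u1 <- frame_i[, 2]; v1 <- frame_i[, 3]
  t2 <- frame_i1[, 1]; u2 <- frame_i1[, 2]; v2 <- frame_i1[, 3]
  ct <- max(-1, min(1, sum(t1 * t2)))
  theta <- acos(ct)
  if (theta > pi - 1e-3) {
    return(list(theta = theta,
                phi = if (is.null(prev_phi)) NA_real_ else prev_phi,
                gimbal = TRUE))
  }
  # phi = alpha + gamma: atan2((R21 - R12), (R11 + R22)) of the relative
  # rotation written in the (u, v, t) axes
  phi <- atan2(sum(v1 * u2) - sum(u1 * v2), sum(u1 * u2) + sum(v1 * v2))
  list(theta = theta, phi = phi, gimbal = FALSE)
}

#' Elastic energy of one joint
#'
#' `E = g_b (1 - cos theta) + g_t (1 - cos phi)`: non-negative, zero only
#' for coincident frames, and quadratic (`~ g x^2 / 2`) for small angles.
#'
#' @param angles list from [bend_twist_angles()].
#' @param params an [elastic_params()].
#' @export
elastic_energy <- function(angles, params) {
  phi <- if (is.na(angles$phi %||% NA_real_)) 0 else angles$phi
  params$g_b * (1 - cos(angles$theta)) + params$g_t * (1 - cos(phi))
}

#' Restoring torque between two connected segments
#'
#' The negative rotational gradient of the joint elastic energy, split into
#' the equal-and-opposite pure torques acting on the two bodies. In terms of
#' the two tangents the torque on the distal body (`i+1`) is
#'
#' `Gamma = -g_t sin(phi) (t_i + t_{i+1}) / (1 + cos(theta)) - g_b (t_i x t_{i+1})`
#'
#' obtained by differentiating `E(theta, phi)` through the dual basis of the
#' ZXZ Euler axes; the proximal body receives `-Gamma`. The twist part acts
#' along the bisector of the tangents, the bending part along their common
#' normal.
#'
#' @inheritParams bend_twist_angles
#' @param params an [elastic_params()].
#' @return list with `torque_i`, `torque_i1` (world-frame 3-vectors),
#'   `angles`.
#' @export
restoring_torque <- function(frame_i, frame_i1, params, prev_phi = NULL) {
  ang <- bend_twist_angles(frame_i, frame_i1, prev_phi = prev_phi)
  t1 <- frame_i[, 1]; t2 <- frame_i1[, 1]
  ct <- cos(ang$theta)
  if (ang$gimbal || 1 + ct < 1e-9) {
    # elastically forbidden at realistic rigidities; deterministic zero-twist
    # fallback keeps the step defined
    g2 <- -params$g_b * cross3(t1, t2)
    return(list(torque_i = -g2, torque_i1 = g2, angles = ang))
  }
  phi <- ang$phi
  g2 <- -params$g_t * sin(phi) * (t1 + t2) / (1 + ct) -
    params$g_b * cross3(t1, t2)
  list(torque_i = -g2, torque_i1 = g2, angles = ang)
}
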