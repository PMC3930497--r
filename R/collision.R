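#' Closest points between two segments
#'
#' Robust closed-form closest-point computation between segments
#' `p1 + s*(q1-p1)` and `p2 + t*(q2-p2)`, `s, t` clamped to `[0, 1]`
#' (Ericson's algorithm). Degenerate (zero-length) segments are handled.
#'
#' @param p1,q1,p2,q2 segment endpoints (3-vectors).
#' @return list with distance `d`, parameters `s`, `t` and the closest
#'   points `c1`, `c2`.
#' @export
segment_closest_points <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  EPS <- 1e-14
  if (a <= EPS && e <= EPS) {
    s <- 0; t <- 0
  } else if (a <= EPS) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c0 <- sum(d1 * r)
    if (e <= EPS) {
      t <- 0; s <- min(max(-c0 / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > EPS) min(max((b * f - c0 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(max(-c0 / a, 0), 1)
      } else if (t > 1) {
        t <- 1; s <- min(max((b - c0) / a, 0), 1)
      }
    }
  }
  c1 <- p1 + s * d1; c2 <- p2 + t * d2
  list(d = sqrt(sum((c1 - c2)^2)), s = s, t = t, c1 = c1, c2 = c2)
}

capsule_axis <- function(state, i) {
  hl <- state$shape$length[i] / 2
  tg <- quat_rotate(state$quat[i, ], c(0, 0, 1))
  list(p = state$pos[i, ] - hl * tg, q = state$pos[i, ] + hl * tg, t = tg)
}

new_contact <- function(body_1, body_2, point, normal, depth, state) {
  r1 <- point - if (body_1 > 0) state$pos[body_1, ] else point
  r2 <- point - if (body_2 > 0) state$pos[body_2, ] else point
  list(body_1 = body_1, body_2 = body_2, point = point,
       normal = normal, depth = depth, r1 = r1, r2 = r2)
}

#' Capsule-capsule narrow phase
#'
#' One contact at the midpoint of the closest-approach segment when the
#' axis-to-axis distance drops below the sum of the capsule radii; normal
#' along the closest-approach direction (from body 2 to body 1), depth the
#' surface overlap. Exactly coincident axes get a deterministic fallback
#' normal (the lowest-index axis perpendicular to the segment direction).
#'
#' @param state a [chain_state()].
#' @param i,j capsule body indices.
#' @param radius_sum sum of the two capsule radii (defaults to the shape
#'   radii).
#' @return a contact list or `NULL`.
#' @export
capsule_capsule_contact <- function(state, i, j, radius_sum = NULL) {
  if (is.null(radius_sum)) {
    radius_sum <- state$shape$radius[i] + state$shape$radius[j]
  }
  ai <- capsule_axis(state, i); aj <- capsule_axis(state, j)
  cp <- segment_closest_points(ai$p, ai$q, aj$p, aj$q)
  if (cp$d >= radius_sum) return(NULL)
  if (cp$d < 1e-12) {
    warning("capsule_capsule_contact(): coincident axes; using fallback normal")
    # deterministic perpendicular of smallest index
    tg <- ai$q - ai$p
    n <- if (abs(tg[1]) <= abs(tg[2]) && abs(tg[1]) <= abs(tg[3])) c(1, 0, 0)
         else if (abs(tg[2]) <= abs(tg[3])) c(0, 1, 0) else c(0, 0, 1)
    n <- n - sum(n * tg) * tg / sum(tg * tg)
    n <- n / sqrt(sum(n^2))
  } else {
    n <- (cp$c1 - cp$c2) / cp$d    # from body j (2) toward body i (1)
  }
  new_contact(i, j, (cp$c1 + cp$c2) / 2, n, radius_sum - cp$d, state)
}

#' Capsule-plane and capsule-sphere narrow phase
#'
#' The plane is the anchoring surface z = 0 (normal +z); the sphere is the
#' magnetic bead. Contact when the lowest capsule surface point dips below
#' the plane, resp. when the axis-to-centre distance drops below the sum of
#' radii.
#'
#' @inheritParams capsule_capsule_contact
#' @param i capsule body index.
#' @export
capsule_plane_contact <- function(state, i) {
  r <- state$shape$radius[i]
  a <- capsule_axis(state, i)
  zmin <- min(a$p[3], a$q[3])
  if (zmin - r >= 0) return(NULL)
  pt <- if (a$p[3] <= a$q[3]) a$p else a$q
  new_contact(i, 0L, c(pt[1], pt[2], zmin - r), c(0, 0, 1), r - zmin, state)
}

#' @rdname capsule_plane_contact
#' @param j sphere (bead) body index.
#' @export
capsule_sphere_contact <- function(state, i, j) {
  r <- state$shape$radius[i]; R <- state$shape$radius[j]
  a <- capsule_axis(state, i)
  ctr <- state$pos[j, ]
  cp <- segment_closest_points(a$p, a$q, ctr, ctr)
  if (cp$d >= r + R) return(NULL)
  n <- if (cp$d > 1e-12) (cp$c1 - ctr) / cp$d else c(0, 0, 1)
  pt <- ctr + n * (R + (cp$d - R - r) / 2)
  new_contact(i, j, pt, n, r + R - cp$d, state)
}

#' @rdname capsule_plane_contact
#' @export
sphere_plane_contact <- function(state, i) {
  R <- state$shape$radius[i]
  z <- state$pos[i, 3]
  if (z - R >= 0) return(NULL)
  new_contact(i, 0L, c(state$pos[i, 1], state$pos[i, 2], z - R),
              c(0, 0, 1), R - z, state)
}

#' Broad-phase candidate pairs
#'
#' Uniform spatial hash grid with cell size `cutoff`: bodies are binned by
#' centre position and only pairs sharing a 27-cell neighbourhood are
#' reported. Returns a superset of all pairs within `cutoff`, excluding
#' permanently attached pairs: chain-adjacent bodies, and (when flagged) the
#' first-cylinder/plane and last-cylinder/bead pairs.
#'
#' @param state a [chain_state()].
#' @param cutoff grid cell size; must cover `b + 2 r`.
#' @param exclude two-column matrix of body-index pairs never reported.
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
broad_phase <- function(state, cutoff, exclude = NULL) {
  n <- n_bodies(state)
  if (n < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  cell <- floor(state$pos / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  excl_key <- character(0)
  if (!is.null(exclude)) {
    excl_key <- paste(pmin(exclude[, 1], exclude[, 2]),
                      pmax(exclude[, 1], exclude[, 2]))
  }
  # map cells to member lists, then scan each body's 27-neighbourhood
  cell_map <- split(seq_len(n), key)
  out <- list()
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(cell[i, 1] + dx, cell[i, 2] + dy, cell[i, 3] + dz)
      cand <- c(cand, cell_map[[k]])
    }
    cand <- cand[cand > i]
    if (length(cand)) out[[length(out) + 1L]] <- cbind(i, cand)
  }
  if (!length(out)) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  prs <- do.call(rbind, out)
  keep <- !(paste(prs[, 1], prs[, 2]) %in% excl_key)
  prs <- prs[keep, , drop = FALSE]
  colnames(prs) <- c("i", "j")
  prs
}

#' Bonded-neighbour exclusion window
#'
#' Chain neighbours within `|i - j| <= window` never collide: the joint
#' geometry forces their capsules to overlap permanently (for adjacent
#' bodies at the shared joint; for further neighbours whenever the capsule
#' diameter exceeds the contour gap `|i - j| - 1`, as happens with the fat
#' low-salt effective radius). Treating those built-in overlaps as contacts
#' would pit the contact rows against the joints.
#'
#' @param radius capsule radius in b units.
#' @export
bonded_exclusion_window <- function(radius) {
  max(1L, as.integer(floor(2 * radius + 1 - 1e-9)))
}

#' Detect all contacts in an assembly
#'
#' Runs the broad phase over the chain (plus bead) and the narrow-phase
#' tests against the plane and between candidate pairs. Chain-adjacent
#' pairs, the first-cylinder/plane pair and the last-cylinder/bead pair are
#' permanently excluded (they are joined and would otherwise always
#' overlap at the joint).
#'
#' @param state a [chain_state()].
#' @param plane logical: include the z = 0 anchoring plane.
#' @param first_plane_attached,bead_index assembly attachment metadata.
#' @return list of contacts.
#' @export
detect_contacts <- function(state, plane = TRUE, first_plane_attached = TRUE,
                            bead_index = NA_integer_) {
  n <- n_bodies(state)
  caps <- which(state$shape$type == "capsule")
  win <- bonded_exclusion_window(max(state$shape$radius[caps]))
  excl <- NULL
  for (w in seq_len(win)) {
    k <- length(caps) - w
    if (k >= 1) excl <- rbind(excl, cbind(caps[1:k], caps[1:k + w]))
  }
  if (!is.na(bead_index)) {
    for (w in seq_len(win)) {
      k <- length(caps) - w + 1L
      if (k >= 1) excl <- rbind(excl, c(caps[k], bead_index))
    }
  }
  cutoff <- max(state$shape$length + 2 * state$shape$radius)
  prs <- broad_phase(state, cutoff, exclude = excl)
  contacts <- list()
  add <- function(ct) if (!is.null(ct)) contacts[[length(contacts) + 1L]] <<- ct
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, 1]; j <- prs[r, 2]
    ti <- state$shape$type[i]; tj <- state$shape$type[j]
    if (ti == "capsule" && tj == "capsule") add(capsule_capsule_contact(state, i, j))
    else if (ti == "capsule") add(capsule_sphere_contact(state, i, j))
    else if (tj == "capsule") add(capsule_sphere_contact(state, j, i))
  }
  if (plane) {
    for (i in seq_len(n)) {
      if (first_plane_attached && i %in% caps[seq_len(win)]) next
      ct <- if (state$shape$type[i] == "capsule") capsule_plane_contact(state, i)
            else sphere_plane_contact(state, i)
      add(ct)
    }
  }
  contacts
}

#' Contact constraint rows
#'
#' Converts detected contacts into unilateral constraint rows: the row
#' Jacobian is the relative normal velocity `n . (v1 + w1 x r1 - v2 - w2 x r2)`,
#' the target velocity `(erp/dt) * depth` pushes the bodies apart, and the
#' multiplier is bounded below by zero (push only; restitution 0, no
#' friction).
#'
#' @param contacts list from [detect_contacts()].
#' @param erp error-reduction parameter used for the push-out term.
#' @param dt timestep.
#' @return list with per-row `C` (= `-depth`), `v_target`, `lo`, `hi`.
#' @export
contact_rows <- function(contacts, erp, dt) {
  k <- length(contacts)
  list(C = vapply(contacts, function(ct) -ct$depth, 1.0),
       v_target = numeric(k),  # push-out handled through C and erp
       lo = rep(0, k), hi = rep(Inf, k))
}
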