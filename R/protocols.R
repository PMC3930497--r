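#' Force-extension protocol
#'
#' For each stretching force: equilibrate, then sample the extension (the
#' distance from the anchor plane to the distal chain end) and report its
#' mean and autocorrelation-corrected standard error. Forces may be given
#' in pN or directly in reduced units.
#'
#' @param assembly a tweezers [build_assembly()] (or FJC-mode chain).
#' @param forces_pN stretching forces in pN (converted through the
#'   assembly's unit system); alternatively supply `forces_reduced`.
#' @param forces_reduced forces in kBT/b units (overrides `forces_pN`).
#' @param equil_steps,sample_steps steps to discard / to sample per force.
#' @param thermostat a [thermostat_params()].
#' @param seed base seed; each force uses `seed + index`.
#' @param collisions enable excluded volume.
#' @param obs_stride sampling stride in steps.
#' @param dt timestep.
#' @param init_boltzmann start each force from an exact Boltzmann draw via
#'   [sample_chain_configuration()] (freely-jointed chains only); removes
#'   the slow configurational equilibration.
#' @param replicas number of independent replicas per force. With
#'   `init_boltzmann = TRUE` each replica starts from its own exact draw,
#'   so the across-replica mean is unbiased and its standard error is free
#'   of slow-mode autocorrelation; with one replica the batch-means SE is
#'   used instead.
#' @return a tibble of class `fe_curve`: one row per force with
#'   `force_pN`, `force`, `x` (= f b/kBT), `z_mean`, `z_se`, `rel_ext`,
#'   `rel_ext_se`, `n_eff`, `drift`.
#' @export
run_force_extension <- function(assembly, forces_pN = NULL,
                                forces_reduced = NULL,
                                equil_steps = 2e5, sample_steps = 1e6,
                                thermostat = thermostat_params("global"),
                                seed = 1, collisions = TRUE,
                                obs_stride = 100L, dt = 0.000592,
                                init_boltzmann = FALSE, replicas = 1L) {
  if (is.null(forces_reduced)) {
    if (is.null(forces_pN)) stop("run_force_extension(): supply forces",
                                 call. = FALSE)
    forces_reduced <- force_pN_to_reduced(forces_pN, assembly$units)
  } else if (is.null(forces_pN)) {
    forces_pN <- force_reduced_to_pN(forces_reduced, assembly$units)
  }
  one_replica <- function(f, i, rep_k) {
    asm <- assembly
    sd0 <- seed + 1000L * i + 31L * rep_k
    if (init_boltzmann) {
      asm <- sample_chain_configuration(asm, force = f, seed = sd0 + 7L)
    }
    eq <- run_simulation(asm, equil_steps, dt = dt, thermostat = thermostat,
                         seed = sd0, collisions = collisions,
                         force = f, obs_stride = obs_stride, wr_stride = 0L)
    run_simulation(eq$assembly, sample_steps, dt = dt,
                   thermostat = thermostat, seed = sd0 + 1L,
                   collisions = collisions, force = f,
                   obs_stride = obs_stride, wr_stride = 0L)
  }
  rows <- purrr::map2(forces_reduced, seq_along(forces_reduced), function(f, i) {
    if (replicas > 1L) {
      means <- vapply(seq_len(replicas), function(k)
        mean(one_replica(f, i, k)$observables$ext[-1]), 1.0)
      tibble::tibble(force = f, z_mean = mean(means),
                     z_se = stats::sd(means) / sqrt(replicas),
                     n_eff = replicas, drift = FALSE)
    } else {
      sm <- one_replica(f, i, 1L)
      bs <- batch_stats(sm$observables$ext[-1])
      tibble::tibble(force = f, z_mean = bs$mean, z_se = bs$se,
                     n_eff = bs$n_eff, drift = bs$drift)
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    force_pN = forces_pN, x = .data$force,
    rel_ext = .data$z_mean / assembly$L0,
    rel_ext_se = .data$z_se / assembly$L0,
    .before = 1)
  if (any(out$drift)) {
    warning("run_force_extension(): drift test flagged ",
            sum(out$drift), " force point(s) as possibly non-equilibrated")
  }
  class(out) <- c("fe_curve", class(out))
  out
}

#' Turn-clamp (rotation-extension) protocol
#'
#' Drives the bead rotation to each requested number of turns at a slow
#' quasi-static ramp, equilibrates, and samples extension, twist and
#' writhe: the "hat curve" of a magnetic-tweezers experiment at fixed
#' force. Turn values are visited sequentially within each sign branch
#' (0 -> n1 -> n2 ...), carrying the supercoiled state along the ramp.
#'
#' @param assembly a tweezers assembly with a bead and a weld anchor (both
#'   ends torsionally constrained).
#' @param force_pN stretching force in pN (or use `force_reduced`).
#' @param turns numeric vector of bead turns (may mix signs).
#' @param force_reduced force in kBT/b.
#' @param ramp_rate turns per 1000 steps (default 0.05).
#' @param equil_steps,sample_steps steps after each ramp / sampled.
#' @inheritParams run_force_extension
#' @param wr_stride writhe evaluation stride (in logged rows).
#' @return tibble of class `hat_curve`: per turn value `n`, `sigma`,
#'   `z_mean`, `z_se`, `rel_ext`, `Tw`, `Wr`, `lk_residual`
#'   (`n - (dTw + dWr)`, White's-theorem check), `n_eff`, `drift`.
#' @export
run_turn_clamp <- function(assembly, force_pN = NULL, turns = 0,
                           force_reduced = NULL, ramp_rate = 0.05,
                           equil_steps = 2e5, sample_steps = 5e5,
                           thermostat = thermostat_params("global"),
                           seed = 1, collisions = TRUE,
                           obs_stride = 100L, wr_stride = 10L,
                           dt = 0.000592) {
  if (is.na(assembly$bead_index) || assembly$anchor != "weld") {
    stop("run_turn_clamp(): needs a bead and a weld anchor", call. = FALSE)
  }
  f <- if (is.null(force_reduced)) {
    force_pN_to_reduced(force_pN, assembly$units)
  } else force_reduced

  # reference topology of the build
  tw0 <- sum(assembly$phi_cum) / (2 * pi)
  wr0 <- twist_writhe(assembly)$Wr

  branch <- function(nvals, seed_off) {
    asm <- assembly
    out <- list()
    for (i in seq_along(nvals)) {
      n_target <- nvals[i]
      d_turns <- abs(n_target - asm$psi_target / (2 * pi))
      ramp_steps <- ceiling(d_turns / ramp_rate * 1000)
      if (ramp_steps > 0) {
        rr <- run_simulation(asm, ramp_steps, dt = dt, thermostat = thermostat,
                             seed = seed + seed_off + 10L * i,
                             collisions = collisions, force = f,
                             clamp = "turn", turns = n_target,
                             ramp_rate = ramp_rate, obs_stride = obs_stride,
                             wr_stride = 0L)
        asm <- rr$assembly
      }
      eq <- run_simulation(asm, equil_steps, dt = dt, thermostat = thermostat,
                           seed = seed + seed_off + 10L * i + 1L,
                           collisions = collisions, force = f,
                           clamp = "turn", turns = n_target,
                           obs_stride = obs_stride, wr_stride = 0L)
      sm <- run_simulation(eq$assembly, sample_steps, dt = dt,
                           thermostat = thermostat,
                           seed = seed + seed_off + 10L * i + 2L,
                           collisions = collisions, force = f,
                           clamp = "turn", turns = n_target,
                           obs_stride = obs_stride, wr_stride = wr_stride)
      asm <- sm$assembly
      o <- sm$observables[-1, ]
      bs <- batch_stats(o$ext)
      tw <- mean(o$Tw) - tw0
      wr <- mean(o$Wr, na.rm = TRUE) - wr0
      out[[i]] <- tibble::tibble(
        n = n_target, sigma = n_target / assembly$Lk0,
        z_mean = bs$mean, z_se = bs$se,
        rel_ext = bs$mean / assembly$L0, rel_ext_se = bs$se / assembly$L0,
        Tw = tw, Wr = wr, lk_residual = n_target - (tw + wr),
        n_eff = bs$n_eff, drift = bs$drift)
    }
    dplyr::bind_rows(out)
  }

  pos <- sort(unique(turns[turns >= 0]))
  neg <- sort(unique(turns[turns < 0]), decreasing = TRUE)
  out <- dplyr::bind_rows(
    if (length(pos)) branch(pos, 0L),
    if (length(neg)) branch(neg, 5000L)
  )
  out <- dplyr::arrange(out, .data$n)
  out$force <- f
  class(out) <- c("hat_curve", class(out))
  out
}

#' Torque-clamp protocol
#'
#' Applies a constant torque about z to the bead (rotation about z free,
#' tilt locked) and records the average relative overtwist
#' `sigma = bead angle / (2 pi Lk0)` once stationary; the
#' torque-overtwist characteristic of a torque-controlled tweezers
#' experiment. Near the critical torque the overtwist is bistable and the
#' drift flag marks non-stationary points.
#'
#' @param assembly a tweezers assembly with bead and weld anchor.
#' @param torques_kBT torque values in kBT.
#' @inheritParams run_turn_clamp
#' @return tibble of class `torque_curve`: per torque `torque`,
#'   `sigma_mean`, `sigma_se`, `sigma_var`, `z_mean`, `cor_z_sigma`,
#'   `n_eff`, `drift`.
#' @export
run_torque_clamp <- function(assembly, force_pN = NULL, torques_kBT = 0,
                             force_reduced = NULL,
                             equil_steps = 5e5, sample_steps = 1e6,
                             thermostat = thermostat_params("global"),
                             seed = 1, collisions = TRUE,
                             obs_stride = 100L, dt = 0.000592) {
  if (is.na(assembly$bead_index) || assembly$anchor != "weld") {
    stop("run_torque_clamp(): needs a bead and a weld anchor", call. = FALSE)
  }
  f <- if (is.null(force_reduced)) {
    force_pN_to_reduced(force_pN, assembly$units)
  } else force_reduced
  rows <- purrr::imap(as.list(torques_kBT), function(g, i) {
    eq <- run_simulation(assembly, equil_steps, dt = dt,
                         thermostat = thermostat, seed = seed + 100L * i,
                         collisions = collisions, force = f,
                         clamp = "torque", torque = g,
                         obs_stride = obs_stride, wr_stride = 0L)
    sm <- run_simulation(eq$assembly, sample_steps, dt = dt,
                         thermostat = thermostat, seed = seed + 100L * i + 1L,
                         collisions = collisions, force = f,
                         clamp = "torque", torque = g,
                         obs_stride = obs_stride, wr_stride = 0L)
    o <- sm$observables[-1, ]
    bs <- batch_stats(o$sigma)
    tibble::tibble(torque = g, sigma_mean = bs$mean, sigma_se = bs$se,
                   sigma_var = stats::var(o$sigma), z_mean = mean(o$ext),
                   cor_z_sigma = suppressWarnings(stats::cor(o$ext, o$sigma)),
                   n_eff = bs$n_eff, drift = bs$drift)
  })
  out <- dplyr::bind_rows(rows)
  out$force <- f
  class(out) <- c("torque_curve", class(out))
  out
}
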