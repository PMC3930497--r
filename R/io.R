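#' Default configuration
#'
#' The full default configuration tree: `units` (cylinder length, bp per
#' cylinder, temperature, bp mass), `dna` (persistence lengths or explicit
#' rigidities, salt, chain size, bead), `solver`, `thermostat`, `integrator`
#' `collision` and `experiment` sections. [load_config()] merges a YAML
#' file over these defaults and validates the result.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    units = list(b_nm = 3.4, bp_per_cylinder = 10, temperature_K = 298.15,
                 bp_mass_Da = 650),
    dna = list(persistence_length_nm = 50, twist_persistence_length_nm = 95,
               g_b = NULL, g_t = NULL, salt_mM = 100, n_cylinders = 300,
               anchor = "weld", bead = TRUE, bead_radius_nm = 50,
               end_tangency = FALSE),
    solver = list(erp = 0.8, cfm = 1e-10, sor_relaxation = 1.3,
                  sor_iterations = 64, accept_tol = 1e-6,
                  force_direct = FALSE),
    thermostat = list(mode = "global", gamma = 10, seed = 1),
    integrator = list(dt = 0.000592, n_steps = 1e6, output_stride = 100),
    collision = list(enabled = TRUE, cutoff_scale = 1),
    experiment = list(mode = "force-extension", force_pN = 1,
                      turns = list(), torque_kBT = list(),
                      equil_steps = 2e5, sample_steps = 1e6,
                      ramp_rate = 0.05)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, applies the documented defaults for missing
#' keys, and runs cross-field validation (unknown keys and sections,
#' persistence-length vs explicit-rigidity conflicts, ramp rate vs
#' timestep).
#'
#' @param path YAML file path (an empty or missing-key file yields the full
#'   default configuration).
#' @return validated configuration list of class `rbdna_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config(): no such file: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop("load_config(): unknown section(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad)) stop("load_config(): unknown key(s) in [", sec, "]: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- merge_config(base, user)
  if (!is.null(user$dna$g_b) && !is.null(user$dna$persistence_length_nm)) {
    stop("load_config(): give either dna.persistence_length_nm or dna.g_b, ",
         "not both", call. = FALSE)
  }
  if (!is.null(user$dna$g_t) && !is.null(user$dna$twist_persistence_length_nm)) {
    stop("load_config(): give either dna.twist_persistence_length_nm or ",
         "dna.g_t, not both", call. = FALSE)
  }
  with(cfg$integrator, if (dt <= 0) stop("integrator.dt must be positive",
                                         call. = FALSE))
  # quasi-static sanity: twist added per joint per step must stay below pi
  dpsi <- 2 * pi * cfg$experiment$ramp_rate / 1000
  if (dpsi >= pi * max(cfg$dna$n_cylinders - 1, 1)) {
    stop("load_config(): experiment.ramp_rate too fast for this chain",
         call. = FALSE)
  }
  structure(cfg, class = c("rbdna_config", "list"))
}

#' Build an assembly from a configuration
#'
#' @param cfg a configuration from [load_config()] or [default_config()].
#' @export
assembly_from_config <- function(cfg) {
  units <- make_unit_system(cfg$units$b_nm, cfg$units$bp_per_cylinder,
                            cfg$units$temperature_K, cfg$units$bp_mass_Da)
  build_assembly(
    n_cylinders = cfg$dna$n_cylinders, salt_mM = cfg$dna$salt_mM,
    units = units, l_p_nm = cfg$dna$persistence_length_nm,
    l_t_nm = cfg$dna$twist_persistence_length_nm,
    g_b = cfg$dna$g_b, g_t = cfg$dna$g_t,
    anchor = cfg$dna$anchor, bead = isTRUE(cfg$dna$bead),
    bead_radius_nm = cfg$dna$bead_radius_nm,
    end_tangency = isTRUE(cfg$dna$end_tangency))
}

#' Write / read a trajectory container
#'
#' Trajectories (per-frame body positions and quaternions) are stored as a
#' columnar Parquet table: columns `frame`, `time`, `body`, `x`, `y`, `z`,
#' `qw`, `qx`, `qy`, `qz`. The round trip is lossless (doubles are stored
#' in binary).
#'
#' @param trajectory the `trajectory` element of a [run_simulation()]
#'   result.
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("write_trajectory(): the arrow package is required", call. = FALSE)
  }
  nf <- dim(trajectory$pos)[1]; nb <- dim(trajectory$pos)[2]
  df <- tibble::tibble(
    frame = rep(seq_len(nf), each = nb),
    time = rep(trajectory$time, each = nb),
    body = rep(seq_len(nb), nf),
    x = as.numeric(t(trajectory$pos[, , 1])),
    y = as.numeric(t(trajectory$pos[, , 2])),
    z = as.numeric(t(trajectory$pos[, , 3])),
    qw = as.numeric(t(trajectory$quat[, , 1])),
    qx = as.numeric(t(trajectory$quat[, , 2])),
    qy = as.numeric(t(trajectory$quat[, , 3])),
    qz = as.numeric(t(trajectory$quat[, , 4]))
  )
  arrow::write_parquet(df, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @param n_cylinders number of chain cylinders (bodies beyond this count
#'   are the bead).
#' @export
read_trajectory <- function(path, n_cylinders = NULL) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("read_trajectory(): the arrow package is required", call. = FALSE)
  }
  df <- arrow::read_parquet(path)
  nf <- max(df$frame); nb <- max(df$body)
  ord <- order(df$frame, df$body)
  df <- df[ord, ]
  shape <- function(col) matrix(df[[col]], nf, nb, byrow = TRUE)
  pos <- array(0, c(nf, nb, 3)); quat <- array(0, c(nf, nb, 4))
  pos[, , 1] <- shape("x"); pos[, , 2] <- shape("y"); pos[, , 3] <- shape("z")
  quat[, , 1] <- shape("qw"); quat[, , 2] <- shape("qx")
  quat[, , 3] <- shape("qy"); quat[, , 4] <- shape("qz")
  list(pos = pos, quat = quat,
       time = df$time[!duplicated(df$frame)],
       n_cylinders = if (is.null(n_cylinders)) nb else n_cylinders)
}

#' Write observables to CSV
#'
#' @param observables tibble from [run_simulation()].
#' @param path output CSV.
#' @export
write_observables <- function(observables, path) {
  readr::write_csv(observables, path)
  invisible(path)
}

#' XYZ export of a trajectory
#'
#' One pseudo-atom per cylinder end plus the bead centre per frame, for
#' external molecular viewers. Line count is
#' `frames * (n_cylinders + 1 + has_bead + 2)` including the two header
#' lines per frame.
#'
#' @param trajectory trajectory list.
#' @param path output `.xyz` file.
#' @export
write_xyz <- function(trajectory, path) {
  nf <- dim(trajectory$pos)[1]
  nb <- dim(trajectory$pos)[2]
  n <- trajectory$n_cylinders
  has_bead <- nb > n
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in seq_len(nf)) {
    pts <- matrix(0, n + 1, 3)
    for (i in seq_len(n)) {
      q <- trajectory$quat[fr, i, ]
      tg <- quat_rotate(q, c(0, 0, 0.5))
      p <- trajectory$pos[fr, i, ]
      if (i == 1) pts[1, ] <- p - tg
      pts[i + 1, ] <- p + tg
    }
    nat <- n + 1 + as.integer(has_bead)
    writeLines(c(as.character(nat),
                 sprintf("frame %d t= %.6f", fr, trajectory$time[fr])), con)
    writeLines(sprintf("C %.6f %.6f %.6f", pts[, 1], pts[, 2], pts[, 3]), con)
    if (has_bead) {
      bp <- trajectory$pos[fr, nb, ]
      writeLines(sprintf("O %.6f %.6f %.6f", bp[1], bp[2], bp[3]), con)
    }
  }
  invisible(path)
}

#' Run manifest
#'
#' Records the fully resolved configuration, package version, seed and
#' output checksums so a run can be reproduced bit for bit.
#'
#' @param cfg resolved configuration.
#' @param seed RNG seed.
#' @param outputs character vector of output file paths.
#' @param path manifest YAML path.
#' @export
write_manifest <- function(cfg, seed, outputs, path) {
  hashes <- vapply(outputs, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }, "x")
  man <- list(
    package = "rbdna",
    version = as.character(utils::packageVersion("rbdna")),
    seed = seed,
    config = unclass(cfg),
    outputs = as.list(stats::setNames(hashes, basename(outputs)))
  )
  yaml::write_yaml(man, path)
  invisible(path)
}
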