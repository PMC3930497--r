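#' Plot methods for protocol curves
#'
#' `autoplot()` methods render the three experiment curves the way they
#' are usually shown: force-extension on a log force axis against the WLC
#' and FJC reference laws, rotation-extension ("hat") curves, and the
#' torque-overtwist characteristic.
#'
#' @param object a curve tibble from [run_force_extension()],
#'   [run_turn_clamp()] or [run_torque_clamp()].
#' @param l_p persistence length in b units for the WLC reference line.
#' @param ... unused.
#' @name curve-plots
NULL

#' @rdname curve-plots
#' @export
autoplot.fe_curve <- function(object, l_p = 50 / 3.4, ...) {
  zz <- seq(0.05, 0.97, length.out = 200)
  ref <- tibble::tibble(rel_ext = zz, force = wlc_interpolation_force(zz, l_p))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rel_ext, y = .data$force)) +
    ggplot2::geom_line(data = ref, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$rel_ext - .data$rel_ext_se,
      xmax = .data$rel_ext + .data$rel_ext_se), colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "relative extension z/L0",
                  y = "force (kBT/b)",
                  title = "Force-extension",
                  subtitle = "points: simulation; line: WLC interpolation") +
    ggplot2::theme_minimal()
}

#' @rdname curve-plots
#' @export
autoplot.hat_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$rel_ext)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$rel_ext - .data$rel_ext_se,
      ymax = .data$rel_ext + .data$rel_ext_se)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "bead turns n", y = "relative extension z/L0",
                  title = "Rotation-extension (hat) curve") +
    ggplot2::theme_minimal()
}

#' @rdname curve-plots
#' @export
autoplot.torque_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma_mean, y = .data$torque)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$sigma_mean - .data$sigma_se,
      xmax = .data$sigma_mean + .data$sigma_se)) +
    ggplot2::labs(x = "mean overtwist sigma", y = "torque (kBT)",
                  title = "Torque-overtwist characteristic") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of an engine run
#'
#' Kinetic energy, extension and constraint quality against time.
#'
#' @param run an [run_simulation()] result.
#' @export
plot_run_diagnostics <- function(run) {
  o <- run$observables
  d <- tidyr::pivot_longer(
    dplyr::select(o, "time", "E_kin", "ext", "max_C"),
    -"time", names_to = "observable", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (tau)", y = NULL) +
    ggplot2::theme_minimal()
}
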