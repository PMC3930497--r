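#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` a one-row
#' model summary.
#'
#' @param x a `relax_fit`, `persistence_fit`, `hat_fit` or `affine_fit`.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.relax_fit <- function(x, ...) {
  tibble::tibble(term = "tau", estimate = x$tau,
                 conf.low = min(x$tau_lo, x$tau_hi),
                 conf.high = max(x$tau_lo, x$tau_hi))
}

#' @rdname tidiers
#' @export
glance.relax_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(tau = x$tau, r.squared = s$r.squared, n_lags = x$n_lags)
}

#' @rdname tidiers
#' @export
tidy.persistence_fit <- function(x, ...) {
  ci <- suppressMessages(stats::confint(x$fit))["s", ]
  tibble::tibble(term = "l_p", estimate = x$l_p,
                 conf.low = -x$b / ci[[1]], conf.high = -x$b / ci[[2]])
}

#' @rdname tidiers
#' @export
glance.persistence_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(l_p = x$l_p, r.squared = s$r.squared, n_points = x$n_points)
}

#' @rdname tidiers
#' @export
tidy.hat_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = c("q", "intercept"),
                 estimate = c(x$q, x$intercept),
                 std.error = cf[c("n", "(Intercept)"), "Std. Error"])
}

#' @rdname tidiers
#' @export
glance.hat_fit <- function(x, ...) {
  tibble::tibble(q = x$q, r.squared = x$r2, window = x$window,
                 branch = x$branch)
}

#' @rdname tidiers
#' @export
tidy.affine_fit <- function(x, ...) {
  tibble::tibble(term = c("xi_p", "sigma_star"),
                 estimate = c(x$xi_p, x$sigma_star))
}

#' @rdname tidiers
#' @export
glance.affine_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(xi_p = x$xi_p, sigma_star = x$sigma_star,
                 r.squared = s$r.squared)
}
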