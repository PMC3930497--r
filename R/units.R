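#' Reduced-unit system for the DNA model
#'
#' All internal computation uses reduced units in which the cylinder length
#' `b`, the cylinder mass `m` and the thermal energy `kBT` are 1; SI enters
#' only at the I/O boundary. The derived natural time unit is
#' `tau = b * sqrt(m / kBT)`, the force unit is `kBT / b` and the torque unit
#' is `kBT`.
#'
#' @param b_nm cylinder length in nanometres (3.4 nm, one helix pitch of
#'   10 bp, by default).
#' @param bp_per_cylinder base pairs per cylinder.
#' @param temperature_K bath temperature in kelvin.
#' @param bp_mass_Da mass of one base pair in daltons (650 by default).
#' @param mass_kg optional explicit cylinder mass in kg, overriding
#'   `bp_per_cylinder * bp_mass_Da`.
#' @return an object of class `unit_system` with fields `b_m`, `mass_kg`,
#'   `kBT_J`, `tau_s`, `force_N`, `torque_J` and the inputs.
#' @examples
#' us <- make_unit_system()
#' us$tau_s                       # ~1.7e-10 s
#' from_SI(us, 1e-12, "force")    # 1 pN in kBT/b units
#' @export
make_unit_system <- function(b_nm = 3.4, bp_per_cylinder = 10,
                             temperature_K = 298.15, bp_mass_Da = 650,
                             mass_kg = NULL) {
  if (b_nm <= 0 || bp_per_cylinder < 1 || temperature_K <= 0 ||
      bp_mass_Da <= 0 || (!is.null(mass_kg) && mass_kg <= 0)) {
    stop("make_unit_system(): all parameters must be positive and ",
         "bp_per_cylinder >= 1", call. = FALSE)
  }
  kB <- 1.380649e-23     # J/K
  dalton <- 1.66053906660e-27  # kg
  b_m <- b_nm * 1e-9
  m <- if (is.null(mass_kg)) bp_per_cylinder * bp_mass_Da * dalton else mass_kg
  kBT <- kB * temperature_K
  tau <- b_m * sqrt(m / kBT)
  structure(list(
    b_nm = b_nm, bp_per_cylinder = bp_per_cylinder,
    temperature_K = temperature_K, bp_mass_Da = bp_mass_Da,
    b_m = b_m, mass_kg = m, kBT_J = kBT, tau_s = tau,
    force_N = kBT / b_m, torque_J = kBT
  ), class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system>\n")
  cat(sprintf("  b    = %.4g m (%g nm, %d bp)\n", x$b_m, x$b_nm,
              x$bp_per_cylinder))
  cat(sprintf("  m    = %.4g kg\n", x$mass_kg))
  cat(sprintf("  kBT  = %.4g J (T = %g K)\n", x$kBT_J, x$temperature_K))
  cat(sprintf("  tau  = %.4g s\n", x$tau_s))
  cat(sprintf("  f0   = %.4g N (kBT/b), torque unit = kBT\n", x$force_N))
  invisible(x)
}

unit_scale <- function(units, quantity) {
  switch(quantity,
    length = units$b_m,
    mass = units$mass_kg,
    energy = units$kBT_J,
    torque = units$torque_J,
    time = units$tau_s,
    force = units$force_N,
    velocity = units$b_m / units$tau_s,
    stop("unknown quantity: ", quantity, call. = FALSE)
  )
}

#' Convert between SI and reduced units
#'
#' `from_SI()` maps an SI value into reduced units; `to_SI()` is its exact
#' inverse. Conversions round-trip to machine precision.
#'
#' @param units a [make_unit_system()] object.
#' @param x numeric values.
#' @param quantity one of `"length"`, `"mass"`, `"energy"`, `"torque"`,
#'   `"time"`, `"force"`, `"velocity"`.
#' @export
from_SI <- function(units, x, quantity = "length") x / unit_scale(units, quantity)

#' @rdname from_SI
#' @export
to_SI <- function(units, x, quantity = "length") x * unit_scale(units, quantity)

#' Stretching force conversion helpers
#'
#' Magnetic-tweezers forces are quoted in piconewtons; internally the force
#' unit is `kBT/b` (about 1.21 pN for b = 3.4 nm at 298 K).
#'
#' @param f_pN force in pN.
#' @param units a [make_unit_system()] object.
#' @export
force_pN_to_reduced <- function(f_pN, units = make_unit_system()) {
  f_pN * 1e-12 / units$force_N
}

#' @rdname force_pN_to_reduced
#' @param f_red force in reduced units.
#' @export
force_reduced_to_pN <- function(f_red, units = make_unit_system()) {
  f_red * units$force_N * 1e12
}
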