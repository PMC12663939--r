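#' Physical constants for leaf psychrometrics
#'
#' Bundle of the constants that tie water potential, equivalent relative
#' humidity and vapor mole fraction together. All downstream conversions
#' take a `constants` argument so alternative values (e.g. a site-specific
#' atmospheric pressure) can be threaded through a whole analysis.
#'
#' @param gas_constant Universal gas constant, J mol-1 K-1.
#' @param molar_volume_water Molar volume of liquid water, m3 mol-1.
#' @param atm_pressure Atmospheric pressure, kPa.
#' @param turgor_loss_point Water potential at turgor loss, MPa (negative).
#'
#' @return An object of class `physical_constants` (a named list).
#' @examples
#' cst <- physical_constants()
#' psi_to_h(-2, constants = cst)
#' @export
physical_constants <- function(gas_constant = 8.314,
                               molar_volume_water = 1.805e-5,
                               atm_pressure = 101.325,
                               turgor_loss_point = -2) {
  stopifnot(gas_constant > 0, molar_volume_water > 0, atm_pressure > 0)
  if (turgor_loss_point >= 0) {
    stop("turgor_loss_point must be negative (MPa)")
  }
  structure(
    list(
      gas_constant = gas_constant,
      molar_volume_water = molar_volume_water,
      atm_pressure = atm_pressure,
      turgor_loss_point = turgor_loss_point
    ),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  R      = %.4g J/mol/K\n", x$gas_constant))
  cat(sprintf("  Vw     = %.4g m3/mol\n", x$molar_volume_water))
  cat(sprintf("  P_atm  = %.4g kPa\n", x$atm_pressure))
  cat(sprintf("  psi_TLP= %.3g MPa\n", x$turgor_loss_point))
  invisible(x)
}

# MPa of water potential per unit of ln(h) at temperature T (kelvin):
# R*T/Vw expressed in MPa. At 298.15 K this is ~137.3 MPa.
psi_scale_mpa <- function(T, constants = physical_constants()) {
  constants$gas_constant * T / constants$molar_volume_water * 1e-6
}

#' Saturation vapor pressure and mole fraction
#'
#' Saturation vapor pressure over liquid water, by the Tetens formula
#' (default) or the Buck (1981) formula, and the corresponding mole
#' fraction at total pressure `P`. Tetens is the standard choice in leaf
#' gas-exchange work; Buck is provided as a documented alternative and
#' differs from Tetens by <0.3% over the physiological range.
#'
#' @param T Temperature, kelvin. Must lie in (243, 333) K.
#' @param formula Either `"tetens"` or `"buck"`.
#' @return Saturation vapor pressure, kPa.
#' @examples
#' saturation_vapor_pressure(298.15) # ~3.17 kPa
#' @export
saturation_vapor_pressure <- function(T, formula = c("tetens", "buck")) {
  formula <- match.arg(formula)
  if (any(!is.finite(T)) || any(T <= 243) || any(T >= 333)) {
    stop("temperature out of supported range (243, 333) K")
  }
  tc <- T - 273.15
  switch(formula,
    tetens = 0.6108 * exp(17.27 * tc / (tc + 237.3)),
    buck   = 0.61121 * exp(17.502 * tc / (tc + 240.97))
  )
}

#' @rdname saturation_vapor_pressure
#' @param P Total pressure, kPa.
#' @return `saturation_mole_fraction`: mole fraction of water vapor at
#'   saturation, mol mol-1.
#' @examples
#' saturation_mole_fraction(298.15) # ~0.0313 mol/mol
#' @export
saturation_mole_fraction <- function(T, P = physical_constants()$atm_pressure,
                                     formula = c("tetens", "buck")) {
  if (any(P <= 0)) stop("pressure must be positive")
  saturation_vapor_pressure(T, formula) / P
}

#' Kelvin relation between water potential and equivalent relative humidity
#'
#' `psi_to_h()` maps water potential (MPa) to the equivalent relative
#' humidity h = w/w_sat = exp(psi * Vw / (R * T)); `h_to_psi()` is its exact
#' inverse. Both are strictly increasing; the round trip is exact to
#' numerical precision. Small positive water potentials (up to +0.1 MPa,
#' e.g. measurement noise around saturation) are accepted with a warning.
#'
#' @param psi Water potential, MPa (<= 0 expected).
#' @param h Equivalent relative humidity, dimensionless (> 0).
#' @param T Temperature, kelvin.
#' @param constants A [physical_constants()] object.
#' @return `psi_to_h`: h (dimensionless); `h_to_psi`: psi (MPa).
#' @examples
#' psi_to_h(-10)         # ~0.93
#' h_to_psi(0.93)        # ~-9.97 MPa
#' @export
psi_to_h <- function(psi, T = 298.15, constants = physical_constants()) {
  if (any(psi > 0.1, na.rm = TRUE)) {
    warning("water potential > +0.1 MPa: outside measurement-noise band")
  } else if (any(psi > 0, na.rm = TRUE)) {
    warning("positive water potential treated as measurement noise")
  }
  exp(psi / psi_scale_mpa(T, constants))
}

#' @rdname psi_to_h
#' @export
h_to_psi <- function(h, T = 298.15, constants = physical_constants()) {
  if (any(h <= 0, na.rm = TRUE)) stop("h must be strictly positive")
  log(h) * psi_scale_mpa(T, constants)
}

#' Ambient air state from vapor pressure deficit
#'
#' Converts a leaf-to-air vapor pressure deficit into the ambient water
#' vapor mole fraction, w_a = (e_sat(T_leaf) - VPD) / P, consistent with
#' [saturation_mole_fraction()]. VPD here is defined against saturation at
#' leaf temperature, as in cuvette gas-exchange practice.
#'
#' @param vpd Leaf-to-air vapor pressure deficit, kPa (>= 0).
#' @param T_leaf Leaf temperature, kelvin.
#' @param P Total pressure, kPa.
#' @param formula Saturation formula, see [saturation_vapor_pressure()].
#' @return An object of class `air_state`: list with `temperature` (K),
#'   `w_a` (mol mol-1), `vpd` (kPa), `P` (kPa).
#' @examples
#' air_state_from_vpd(3.8, T_leaf = 303.15)
#' @export
air_state_from_vpd <- function(vpd, T_leaf = 298.15,
                               P = physical_constants()$atm_pressure,
                               formula = c("tetens", "buck")) {
  stopifnot(length(vpd) == 1, length(T_leaf) == 1)
  if (vpd < 0) stop("vpd must be non-negative")
  esat <- saturation_vapor_pressure(T_leaf, formula)
  if (vpd > esat) {
    stop(sprintf(
      "vpd (%.3g kPa) exceeds saturation vapor pressure at T_leaf (%.3g kPa)",
      vpd, esat
    ))
  }
  structure(
    list(
      temperature = T_leaf,
      w_a = (esat - vpd) / P,
      vpd = vpd,
      P = P
    ),
    class = "air_state"
  )
}

#' @export
print.air_state <- function(x, ...) {
  cat(sprintf(
    "Air state: T = %.2f K, VPD = %.3g kPa, w_a = %.4g mol/mol, P = %.4g kPa\n",
    x$temperature, x$vpd, x$w_a, x$P
  ))
  invisible(x)
}
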