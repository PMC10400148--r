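# Unit conversions between gas-phase mixing ratios, partial pressures and
# dissolved concentrations. Convention: total pressure 1 bar at 25 C, so a
# mixing ratio in umol/mol is numerically equal to a partial pressure in ubar.

#' Physical constants used throughout the simulator
#'
#' Gas constant times temperature at 25 C, total molar density of air at
#' 1 bar, and the reference Henry (liquid/gas concentration ratio) partition
#' coefficients for CO2 and O2.
#'
#' @return Named list with `RT` (J mol-1), `P_total` (Pa), `c_total`
#'   (mol m-3 of gas), `henry_co2`, `henry_o2` (dimensionless liquid/gas).
#' @export
physical_constants <- function() {
  RT <- 8.31446 * 298.15
  list(
    RT = RT,
    P_total = 1e5,
    c_total = 1e5 / RT,
    henry_co2 = 0.83,
    henry_o2 = 3.2e-2
  )
}

#' Convert a gas-phase mixing ratio to a dissolved concentration
#'
#' @param ppm mixing ratio in umol/mol (CO2) or mmol/mol * 1000 (O2); equal to
#'   partial pressure in ubar at 1 bar total pressure.
#' @param henry dimensionless liquid/gas partition coefficient.
#' @return concentration in mol m-3 (liquid phase, at gas-liquid equilibrium).
#' @export
ppm_to_liquid <- function(ppm, henry = physical_constants()$henry_co2) {
  k <- physical_constants()
  ppm * 1e-6 * k$P_total / k$RT * henry
}

#' Convert a dissolved concentration back to a gas-equivalent mixing ratio
#'
#' Inverse of [ppm_to_liquid()].
#' @param conc mol m-3 liquid.
#' @param henry dimensionless liquid/gas partition coefficient.
#' @return mixing ratio in umol/mol.
#' @export
liquid_to_ppm <- function(conc, henry = physical_constants()$henry_co2) {
  k <- physical_constants()
  conc / henry * k$RT / k$P_total * 1e6
}

#' Gas-phase concentration (mol m-3) for a mixing ratio
#' @param ppm mixing ratio in umol/mol.
#' @return mol m-3 in the gas phase.
#' @export
ppm_to_gas <- function(ppm) {
  k <- physical_constants()
  ppm * 1e-6 * k$P_total / k$RT
}
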