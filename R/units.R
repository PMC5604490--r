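# Physical constants (CODATA): molar gas constant J/(mol K), Faraday C/mol.
.R_GAS <- 8.31446261815324
.FARADAY <- 96485.33212

#' Thermal energy on the millivolt scale
#'
#' Converts a temperature in degrees Celsius to the thermal energy
#' \eqn{k_B T} expressed in millivolts, i.e. \eqn{1000 \cdot R T / F}.
#' Energies throughout the package are carried in mV so that the
#' thermodynamic cost of transport can be compared directly with
#' membrane-potential scales; at 37 degrees C the value is 26.73 mV.
#'
#' @param temperature_C temperature in degrees Celsius; must be above
#'   absolute zero (-273.15).
#' @return thermal energy in mV (scalar).
#' @examples
#' thermal_energy_mv(37) # ~26.7 mV
#' @export
thermal_energy_mv <- function(temperature_C) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L)
  if (temperature_C < -273.15) {
    stop("temperature below absolute zero (-273.15 C): ", temperature_C)
  }
  1000 * .R_GAS * (temperature_C + 273.15) / .FARADAY
}

#' Convert kJ/mol to millivolts
#'
#' Linear conversion of a molar energy to the per-charge millivolt scale,
#' \eqn{1000 \cdot E / F}; 1 kJ/mol corresponds to 10.36 mV.
#'
#' @param energy_kjmol energy in kJ/mol (vectorised).
#' @return energy in mV.
#' @examples
#' kjmol_to_mv(1) # 10.36
#' @export
kjmol_to_mv <- function(energy_kjmol) {
  1000 * (energy_kjmol * 1000) / .FARADAY
}

#' Salt-bridge equivalents of a network strength
#'
#' Linear registration between the cytoplasmic-network strength expressed
#' as a number of salt-bridge equivalents N (hydrogen bond = 0.5) and the
#' network energy scale in mV: \eqn{\Delta E \approx -130 N - 240}.
#' `mv_to_saltbridges()` is the exact inverse.
#'
#' @param N network interaction energy in salt-bridge equivalents.
#' @param mV network energy scale in millivolts.
#' @return `saltbridges_to_mv()`: energy in mV; `mv_to_saltbridges()`:
#'   salt-bridge equivalents.
#' @examples
#' saltbridges_to_mv(0.7)  # ~ -331 mV
#' mv_to_saltbridges(-330) # ~ 0.69
#' @export
saltbridges_to_mv <- function(N) {
  -130 * N - 240
}

#' @rdname saltbridges_to_mv
#' @export
mv_to_saltbridges <- function(mV) {
  -(mV + 240) / 130
}
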