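#' Temperature-dependent Henry solubility coefficient
#'
#' Henry's-law solubility for freshwater, van 't Hoff temperature dependence:
#' \eqn{K_H(T) = K_H^\circ \exp[d\,(1/T - 1/T^\circ)]} with reference
#' temperature \eqn{T^\circ = 298.15} K. Coefficients are a standard
#' freshwater parameterization (Sander-type compilation); ionic-strength
#' corrections are omitted, which is adequate for stream water.
#'
#' @param analyte one of `"CH4"`, `"CO2"`, `"O2"`.
#' @param temperature water temperature in degrees Celsius; must lie within
#'   the coefficient validity range 0--40 C.
#' @return solubility in mol L\eqn{^{-1}} atm\eqn{^{-1}}.
#' @examples
#' henry_kh("CH4", 20)   # ~0.00155 M/atm
#' @export
henry_kh <- function(analyte, temperature) {
  co <- .henry_coefficients[[match.arg(analyte, names(.henry_coefficients))]]
  if (any(temperature < 0 | temperature > 40))
    stop("temperature outside coefficient validity range (0-40 C)")
  co$kh0 * exp(co$d * (1 / (temperature + 273.15) - 1 / 298.15))
}

# kh0 in mol/(L atm) at 298.15 K; d = -dln(kh)/d(1/T) in K
.henry_coefficients <- list(
  CH4 = list(kh0 = 1.4e-3, d = 1700),
  CO2 = list(kh0 = 3.4e-2, d = 2400),
  O2  = list(kh0 = 1.3e-3, d = 1500)
)

# gas constant, L atm / (mol K)
.R_GAS <- 0.0820573661

#' Dissolved concentration of a gas at equilibrium with an atmosphere
#'
#' Convenience wrapper used for air-equilibrated streamwater and for the
#' 1% CH4 amendment of incubation water.
#'
#' @param analyte gas species.
#' @param partial_pressure partial pressure in atm.
#' @param temperature degrees Celsius.
#' @return dissolved concentration, uM.
#' @export
equilibrium_conc <- function(analyte, partial_pressure, temperature) {
  stopifnot(partial_pressure >= 0)
  henry_kh(analyte, temperature) * partial_pressure * 1e6
}

#' Forward headspace-equilibration model
#'
#' Predicts the gas mixing ratio measured by the analyzer for a water sample
#' of known dissolved concentration, following the two-step protocol: a water
#' volume is equilibrated with an N2 headspace in a closed syringe, then the
#' headspace gas is transferred and diluted with N2 to a final volume before
#' measurement. At equilibrium the dissolved phase obeys Henry's law and the
#' headspace is ideal, so the partial pressure solves the two-phase mass
#' balance
#' \deqn{C_w V_w = K_H\,p\,V_w + p V_g/(RT).}
#'
#' @param C_w dissolved concentration in the original water, uM.
#' @param analyte `"CH4"` or `"CO2"` (O2 also supported).
#' @param water_volume,headspace_volume syringe water and N2 volumes, mL.
#' @param dilution_volume final syringe volume after the N2 top-up, mL; must
#'   be at least `headspace_volume`.
#' @param temperature equilibration temperature, degrees Celsius.
#' @param pressure ambient pressure, atm.
#' @return mixing ratio in ppmv; strictly increasing in `C_w`.
#' @seealso [dissolved_from_headspace()] for the inverse.
#' @export
simulate_headspace <- function(C_w, analyte = "CH4",
                               water_volume = 30, headspace_volume = 30,
                               dilution_volume = 50,
                               temperature = 20, pressure = 1) {
  .check_headspace_geometry(water_volume, headspace_volume, dilution_volume)
  if (any(C_w < 0)) stop("C_w must be non-negative")
  kh <- henry_kh(analyte, temperature)
  vw <- water_volume / 1000      # L
  vg <- headspace_volume / 1000  # L
  n_tot <- C_w * 1e-6 * vw       # mol
  p <- n_tot / (kh * vw + vg / (.R_GAS * (temperature + 273.15)))  # atm
  p_dil <- p * headspace_volume / dilution_volume
  p_dil / pressure * 1e6
}

#' Dissolved gas concentration from a headspace measurement
#'
#' Inverts the headspace-equilibration forward model: given the mixing ratio
#' observed after equilibration and N2 dilution, returns the dissolved
#' concentration in the original water sample. The mass balance is linear in
#' concentration (Henry's law), so the inverse is exact.
#'
#' @param mixing_ratio observed mixing ratio, ppmv.
#' @inheritParams simulate_headspace
#' @return dissolved concentration in the original water, uM.
#' @examples
#' ppm <- simulate_headspace(1.5, "CH4")
#' dissolved_from_headspace(ppm, "CH4")  # 1.5
#' @export
dissolved_from_headspace <- function(mixing_ratio, analyte = "CH4",
                                     water_volume = 30, headspace_volume = 30,
                                     dilution_volume = 50,
                                     temperature = 20, pressure = 1) {
  if (any(mixing_ratio < 0)) stop("mixing_ratio must be non-negative")
  per_uM <- simulate_headspace(1, analyte, water_volume, headspace_volume,
                               dilution_volume, temperature, pressure)
  mixing_ratio / per_uM
}

.check_headspace_geometry <- function(water_volume, headspace_volume,
                                      dilution_volume) {
  if (water_volume <= 0 || headspace_volume <= 0 || dilution_volume <= 0)
    stop("volumes must be positive")
  if (dilution_volume < headspace_volume)
    stop("dilution_volume must be >= headspace_volume")
  invisible(TRUE)
}

#' CH4:CO2 concentration ratio
#'
#' The streamwater CH4:CO2 ratio, used as a proxy for in-situ CH4 production
#' relative to overall respiration.
#'
#' @param site a site record (list or one-row data frame) with fields
#'   `ch4_stream` and `co2_stream` in uM, or a numeric CH4 concentration when
#'   `co2` is given.
#' @param co2 optional CO2 concentration in uM when `site` is numeric.
#' @return unitless ratio.
#' @examples
#' ch4_co2_ratio(0.134, 90)  # ~0.00149
#' @export
ch4_co2_ratio <- function(site, co2 = NULL) {
  if (is.numeric(site) && !is.null(co2)) {
    ch4 <- site
  } else {
    ch4 <- site$ch4_stream
    co2 <- site$co2_stream
  }
  if (any(co2 <= 0)) stop("CO2 concentration must be positive")
  ch4 / co2
}
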