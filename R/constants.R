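#' Physical constants (CODATA 2018)
#'
#' Centralized table of the physical constants used throughout the package,
#' in SI units. Exposed so that every energy/length/velocity conversion in
#' the package traces back to a single, unit-tested source.
#'
#' @format A named list:
#' \describe{
#'   \item{e}{elementary charge, C}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{NA_avogadro}{Avogadro constant, 1/mol}
#'   \item{eps0}{vacuum permittivity, F/m}
#'   \item{F}{Faraday constant, C/mol}
#'   \item{R}{molar gas constant, J/(mol K)}
#'   \item{J_per_kcal}{joules per thermochemical kilocalorie}
#' }
#' @export
#' @examples
#' pk_constants$kB * 295 / pk_constants$e * 1000 # thermal voltage in mV
pk_constants <- list(
  e            = 1.602176634e-19,
  kB           = 1.380649e-23,
  NA_avogadro  = 6.02214076e23,
  eps0         = 8.8541878128e-12,
  F            = 96485.33212,
  R            = 8.31446261815324,
  J_per_kcal   = 4184
)

#' Thermal voltage kB*T/e in millivolts
#'
#' Evaluates to 25.4 mV at 295 K; used by the Kramers voltage-dependence fit
#' and the drift-velocity model.
#'
#' @param temperature_K absolute temperature, K
#' @return thermal voltage in mV
#' @export
#' @examples
#' thermal_voltage_mV(295)
thermal_voltage_mV <- function(temperature_K) {
  stopifnot(temperature_K > 0)
  pk_constants$kB * temperature_K / pk_constants$e * 1e3
}

#' Thermal energy kB*T in kcal/mol
#'
#' @param temperature_K absolute temperature, K
#' @return kB*T expressed per mole, kcal/mol
#' @export
kBT_kcal_mol <- function(temperature_K) {
  stopifnot(temperature_K > 0)
  pk_constants$kB * temperature_K * pk_constants$NA_avogadro / pk_constants$J_per_kcal
}
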