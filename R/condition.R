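#' Experimental condition descriptor
#'
#' A condition bundles the experimental context attached to every trace and
#' fit: buffer pH, KCl concentration, applied transmembrane voltage
#' (trans-positive convention), analyte bulk concentration, and temperature.
#'
#' @param pH buffer pH (unitless)
#' @param salt_M KCl concentration, mol/L; must be > 0
#' @param voltage_mV applied potential, mV (positive = trans-positive); the
#'   regime of interest is +50 to +100 mV but any sign is accepted
#' @param analyte_M analyte bulk concentration, mol/L (>= 0)
#' @param temperature_K absolute temperature, K; must be > 0
#' @param label optional condition label used in reports
#' @return a one-row tibble of class `pore_condition`
#' @export
#' @examples
#' condition(pH = 3, salt_M = 1, voltage_mV = 100, analyte_M = 500e-6)
condition <- function(pH, salt_M, voltage_mV, analyte_M = 0,
                      temperature_K = 295, label = NULL) {
  if (!is.numeric(salt_M) || salt_M <= 0) {
    abort("`salt_M` must be a positive KCl concentration in mol/L.",
          class = "porekin_bad_condition")
  }
  if (!is.numeric(temperature_K) || temperature_K <= 0) {
    abort("`temperature_K` must be positive.", class = "porekin_bad_condition")
  }
  if (!is.numeric(pH) || pH <= 0 || pH >= 14) {
    abort("`pH` must lie in (0, 14).", class = "porekin_bad_condition")
  }
  if (analyte_M < 0) {
    abort("`analyte_M` must be non-negative.", class = "porekin_bad_condition")
  }
  label <- label %||%
    sprintf("pH%g_%gM_%+gmV", pH, salt_M, voltage_mV)
  out <- tibble(
    label = label, pH = pH, salt_M = salt_M, voltage_mV = voltage_mV,
    analyte_M = analyte_M, temperature_K = temperature_K
  )
  class(out) <- c("pore_condition", class(out))
  out
}

#' Default open-pore current for a condition
#'
#' Linear conductance model `I_o = G * dV` with the single-pore conductance
#' scaled linearly with salt concentration, anchored at 1 nS in 1 M KCl so
#' that the open current is ~100 pA at +100 mV in 1 M KCl.
#'
#' @param cond a [condition()] object
#' @param conductance_nS_per_M pore conductance per mol/L of KCl (default 1)
#' @return open current in pA
#' @export
open_current_pA <- function(cond, conductance_nS_per_M = 1) {
  conductance_nS_per_M * cond$salt_M * cond$voltage_mV
}
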