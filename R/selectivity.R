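#' Pitzer activity coefficient for a 1:1 electrolyte
#'
#' Pitzer ion-interaction model for the mean activity coefficient of a
#' symmetric 1:1 salt:
#' `ln gamma = f_g + m B_g + m^2 C_g` with
#' `f_g = -A_phi [sqrt(I)/(1 + b sqrt(I)) + (2/b) ln(1 + b sqrt(I))]`,
#' `B_g = 2 beta0 + (2 beta1 / (alpha^2 I)) [1 - (1 + alpha sqrt(I) -
#' alpha^2 I / 2) exp(-alpha sqrt(I))]` and `C_g = 1.5 C_phi`.
#' Defaults are the standard KCl coefficients at 25 °C (`A_phi = 0.392`);
#' the parameterization is valid up to 6 mol/kg. Molality and molarity are
#' treated interchangeably for KCl at <= 3 M (a documented approximation
#' of ~2–3% in density terms, standard for these buffers).
#'
#' @param molality salt concentration, mol/kg (0 < m <= 6); vectorized
#' @param beta0,beta1,Cphi Pitzer interaction coefficients (KCl defaults
#'   0.04835, 0.2122, -0.00084)
#' @param Aphi Debye–Hückel slope (0.392 at 25 °C)
#' @param b,alpha universal Pitzer constants (1.2, 2.0)
#' @return tibble with `molality`, `gamma` (mean activity coefficient) and
#'   `activity` (`gamma * m`)
#' @export
#' @examples
#' pitzer_activity(c(0.1, 3))$activity # ~0.077, ~1.70
pitzer_activity <- function(molality, beta0 = 0.04835, beta1 = 0.2122,
                            Cphi = -0.00084, Aphi = 0.392, b = 1.2,
                            alpha = 2.0) {
  if (any(molality <= 0) || any(molality > 6)) {
    abort("`molality` must lie in (0, 6] mol/kg (parameterization validity).",
          class = "porekin_bad_argument")
  }
  I <- molality # 1:1 electrolyte: ionic strength equals molality
  sI <- sqrt(I)
  f_g <- -Aphi * (sI / (1 + b * sI) + (2 / b) * log(1 + b * sI))
  B_g <- 2 * beta0 + (2 * beta1 / (alpha^2 * I)) *
    (1 - (1 + alpha * sI - alpha^2 * I / 2) * exp(-alpha * sI))
  C_g <- 1.5 * Cphi
  ln_gamma <- f_g + I * B_g + I^2 * C_g
  gamma <- exp(ln_gamma)
  tibble(molality = molality, gamma = gamma, activity = gamma * molality)
}

#' Ion activities on both sides of the membrane
#'
#' For a single symmetric salt the cation and anion activities coincide on
#' each side; this helper evaluates them from the Pitzer model for a
#' cis/trans KCl gradient.
#'
#' @param cis_M,trans_M KCl concentrations on the grounded cis side and the
#'   trans side, mol/L
#' @return list of class `salt_activities` with `a_K_cis`, `a_K_trans`,
#'   `a_Cl_cis`, `a_Cl_trans`
#' @export
#' @examples
#' salt_activities(0.1, 3)
salt_activities <- function(cis_M, trans_M) {
  a_cis <- pitzer_activity(cis_M)$activity
  a_trans <- pitzer_activity(trans_M)$activity
  structure(
    list(a_K_cis = a_cis, a_K_trans = a_trans,
         a_Cl_cis = a_cis, a_Cl_trans = a_trans),
    class = "salt_activities"
  )
}

#' Reversal potential from an I–V relation
#'
#' Zero-current crossing of the current–voltage relation, by linear
#' interpolation between the bracketing points (default) or from the root
#' of a linear fit. Convention: the returned potential is the applied
#' trans-side potential at zero current, with the cis side grounded.
#'
#' @param iv_points tibble with `voltage_mV` and `current_pA`; the current
#'   must change sign within the voltage range
#' @param method `"interpolate"` (default) or `"fit"`
#' @return reversal potential in mV
#' @export
#' @examples
#' reversal_potential(tibble::tibble(voltage_mV = c(0, 20),
#'                                   current_pA = c(-2, 2))) # 10 mV
reversal_potential <- function(iv_points, method = c("interpolate", "fit")) {
  method <- match.arg(method)
  pts <- arrange(as_tibble(iv_points), .data$voltage_mV)
  if (!all(c("voltage_mV", "current_pA") %in% names(pts))) {
    abort("`iv_points` needs `voltage_mV` and `current_pA` columns.",
          class = "porekin_bad_argument")
  }
  s <- sign(pts$current_pA)
  if (all(s >= 0) || all(s <= 0)) {
    abort("Current does not change sign: no reversal in range.",
          class = "porekin_no_reversal")
  }
  if (method == "fit") {
    fit <- lm(current_pA ~ voltage_mV, data = pts)
    return(unname(-coef(fit)[1] / coef(fit)[2]))
  }
  i <- which(s[-1] * s[-length(s)] <= 0)[1]
  v1 <- pts$voltage_mV[i]; v2 <- pts$voltage_mV[i + 1]
  c1 <- pts$current_pA[i]; c2 <- pts$current_pA[i + 1]
  if (c1 == 0) return(v1)
  v1 + (v2 - v1) * (0 - c1) / (c2 - c1)
}

#' Goldman–Hodgkin–Katz permeability ratio for K+/Cl-
#'
#' Bi-ionic GHK expression for the cation/anion permeability ratio from
#' the reversal potential under a salt gradient:
#' `P_K/P_Cl = (a_Cl_trans - a_Cl_cis exp(psi F / R T)) /
#'             (a_K_trans exp(psi F / R T) - a_K_cis)`.
#' A ratio of 1 corresponds to a non-selective pore (zero reversal
#' potential for symmetric activities); values below 1 indicate anion
#' selectivity. Outside the Nernst window the expression changes sign and
#' a domain error is raised.
#'
#' @param psi_rev_mV reversal potential, mV (trans relative to grounded cis)
#' @param activities a [salt_activities()] object
#' @param temperature_K absolute temperature (default 295 K)
#' @return unitless permeability ratio `P_K / P_Cl`
#' @export
ghk_permeability_ratio <- function(psi_rev_mV, activities,
                                   temperature_K = 295) {
  stopifnot(inherits(activities, "salt_activities"))
  assert_positive_scalar(temperature_K, "temperature_K")
  k <- pk_constants
  ef <- exp(psi_rev_mV * 1e-3 * k$F / (k$R * temperature_K))
  num <- activities$a_Cl_trans - activities$a_Cl_cis * ef
  den <- activities$a_K_trans * ef - activities$a_K_cis
  if (psi_rev_mV == 0 && num == 0 && den == 0) {
    # symmetric activities at zero potential: the expression is 0/0 and any
    # permeability ratio satisfies zero current; return the non-selective
    # value by convention
    return(1)
  }
  if (den == 0) {
    abort("GHK denominator is zero at this reversal potential.",
          class = "porekin_ghk_domain")
  }
  ratio <- num / den
  if (!is.finite(ratio) || ratio <= 0) {
    abort("Reversal potential lies outside the Nernst window: permeability ratio is not positive.",
          class = "porekin_ghk_domain")
  }
  ratio
}

#' Reversal potential implied by a GHK permeability ratio
#'
#' Inverse of [ghk_permeability_ratio()]: root-finds the reversal potential
#' within the Nernst window that reproduces a given permeability ratio.
#' The two functions are mutual inverses to ~1e-9 relative tolerance.
#'
#' @param ratio target `P_K / P_Cl` (> 0)
#' @inheritParams ghk_permeability_ratio
#' @return reversal potential in mV
#' @export
ghk_reversal_potential <- function(ratio, activities, temperature_K = 295) {
  assert_positive_scalar(ratio, "ratio")
  k <- pk_constants
  kT_F_mV <- k$R * temperature_K / k$F * 1e3
  # Nernst window bounds where numerator / denominator vanish
  v_hi <- kT_F_mV * log(activities$a_Cl_trans / activities$a_Cl_cis)
  v_lo <- kT_F_mV * log(activities$a_K_cis / activities$a_K_trans)
  lo <- min(v_lo, v_hi); hi <- max(v_lo, v_hi)
  eps <- (hi - lo) * 1e-12
  f <- function(v) ghk_permeability_ratio(v, activities, temperature_K) - ratio
  uniroot(f, c(lo + eps, hi - eps), tol = 1e-12)$root
}

#' Selectivity report for a cis/trans salt gradient
#'
#' Bundles the Pitzer activities, the reversal potential (measured from an
#' I–V table or supplied directly) and the GHK permeability ratio into one
#' record.
#'
#' @param psi_rev_mV reversal potential, mV; alternatively pass `iv_points`
#' @param iv_points optional I–V tibble forwarded to [reversal_potential()]
#' @param cis_M,trans_M KCl concentrations, mol/L (defaults: the
#'   0.1 M cis / 3 M trans gradient)
#' @param temperature_K absolute temperature (default 295 K)
#' @return one-row tibble: `psi_rev_mV`, `permeability_ratio`,
#'   `a_cis`, `a_trans`, `temperature_K`
#' @export
selectivity_report <- function(psi_rev_mV = NULL, iv_points = NULL,
                               cis_M = 0.1, trans_M = 3,
                               temperature_K = 295) {
  if (is.null(psi_rev_mV)) {
    if (is.null(iv_points)) {
      abort("Provide either `psi_rev_mV` or `iv_points`.",
            class = "porekin_bad_argument")
    }
    psi_rev_mV <- reversal_potential(iv_points)
  }
  act <- salt_activities(cis_M, trans_M)
  tibble(
    psi_rev_mV = psi_rev_mV,
    permeability_ratio = ghk_permeability_ratio(psi_rev_mV, act,
                                                temperature_K),
    a_cis = act$a_K_cis, a_trans = act$a_K_trans,
    temperature_K = temperature_K
  )
}
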