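#' Protonation charge model for a branched polyamine
#'
#' A charge model is a table of basic groups (count, pKa); the net charge
#' at a given pH is the sum of Henderson–Hasselbalch protonated fractions.
#' The default describes a generation-1 PAMAM dendrimer: 8 surface primary
#' amines and 6 internal tertiary amines (4 outer, 2 core). The pKa values
#' are a calibration chosen to reproduce the accepted net charges of this
#' dendrimer (+12 at pH 3, ~+8 at pH 7, nearly neutral at pH 10.3), not a
#' literature table; override freely.
#'
#' @param groups tibble with `count` (positive integers), `pKa`, and an
#'   optional `group` label; every group carries +1 per protonated site
#' @param label model label
#' @return tibble of class `charge_model`
#' @export
charge_model <- function(groups, label = "custom") {
  g <- as_tibble(groups)
  if (!all(c("count", "pKa") %in% names(g)) || any(g$count <= 0)) {
    abort("`groups` needs positive `count` and `pKa` columns.",
          class = "porekin_bad_argument")
  }
  attr(g, "label") <- label
  class(g) <- c("charge_model", class(g))
  g
}

#' @rdname charge_model
#' @export
pamam_g1_charge_model <- function() {
  charge_model(
    tibble(
      group = c("primary", "tertiary_outer", "tertiary_core"),
      count = c(8L, 4L, 2L),
      pKa = c(9.0, 6.0, 1.5)
    ),
    label = "PAMAM-G1"
  )
}

#' Net charge of a protonation model at a given pH
#'
#' `Q(pH) = sum count_j / (1 + 10^(pH - pKa_j))` in units of the elementary
#' charge.
#'
#' @param model a [charge_model()]
#' @param pH pH value(s) in (0, 14)
#' @return numeric valence(s), with the nearest integer as attribute
#'   `"nearest"`
#' @export
#' @examples
#' net_charge(pamam_g1_charge_model(), 3) # ~ +12
net_charge <- function(model, pH) {
  stopifnot(inherits(model, "charge_model"))
  if (any(pH <= 0 | pH >= 14)) {
    abort("`pH` must lie in (0, 14).", class = "porekin_bad_argument")
  }
  q <- vapply(pH, function(p) {
    sum(model$count / (1 + 10^(p - model$pKa)))
  }, numeric(1))
  attr(q, "nearest") <- round(q)
  q
}

#' alpha-hemolysin pore geometry and charge model
#'
#' Default geometry for the heptameric alpha-hemolysin channel: overall
#' length 10 nm, beta-barrel diameter 2.0 nm, constriction 1.5 nm; the
#' analyte (dendrimer) diameter defaults to 1.8 nm. Ring/constriction/
#' vestibule charges are tabulated by pH (in elementary charges): at pH 3
#' the barrel mouth, constriction and vestibule carry +5.5, +6.5 and +28;
#' at pH 7 the mouth carries -7 and the interior is neutral.
#'
#' @param length_nm pore length, nm
#' @param barrel_diameter_nm beta-barrel diameter, nm
#' @param constriction_diameter_nm constriction diameter, nm
#' @param analyte_diameter_nm analyte diameter, nm
#' @param charges_by_pH tibble `pH`, `q_ring`, `q_constr`, `q_vest`
#' @return list of class `pore_model`
#' @export
pore_model <- function(length_nm = 10, barrel_diameter_nm = 2.0,
                       constriction_diameter_nm = 1.5,
                       analyte_diameter_nm = 1.8,
                       charges_by_pH = tibble(
                         pH = c(3, 7),
                         q_ring = c(5.5, -7),
                         q_constr = c(6.5, 0),
                         q_vest = c(28, 0)
                       )) {
  assert_positive_scalar(length_nm, "length_nm")
  assert_positive_scalar(barrel_diameter_nm, "barrel_diameter_nm")
  structure(
    list(length_nm = length_nm, barrel_diameter_nm = barrel_diameter_nm,
         constriction_diameter_nm = constriction_diameter_nm,
         analyte_diameter_nm = analyte_diameter_nm,
         charges_by_pH = charges_by_pH),
    class = "pore_model"
  )
}

#' Debye screening length of an electrolyte
#'
#' `kappa^-1 = sqrt(eps0 epsr kB T / (2 NA e^2 I * 1e3))`, scaling as
#' `I^(-1/2)`; about 0.30 nm in 1 M KCl and 0.43 nm in 0.5 M KCl at 300 K.
#'
#' @param ionic_strength_M ionic strength, mol/L
#' @param temperature_K absolute temperature (default 300 K)
#' @param rel_permittivity relative permittivity (default 78, water)
#' @return Debye length in nm
#' @export
debye_length <- function(ionic_strength_M, temperature_K = 300,
                         rel_permittivity = 78) {
  stopifnot(all(ionic_strength_M > 0), temperature_K > 0,
            rel_permittivity > 0)
  k <- pk_constants
  lam_m <- sqrt(k$eps0 * rel_permittivity * k$kB * temperature_K /
                  (2 * k$NA_avogadro * k$e^2 * ionic_strength_M * 1e3))
  lam_m * 1e9
}

#' Bjerrum length
#'
#' `l_B = e^2 / (4 pi eps0 epsr kB T)`, the separation at which two unit
#' charges interact with thermal energy kBT; ~0.7 nm in water at 300 K.
#'
#' @inheritParams debye_length
#' @return Bjerrum length in nm
#' @export
bjerrum_length <- function(temperature_K = 300, rel_permittivity = 78) {
  stopifnot(temperature_K > 0, rel_permittivity > 0)
  k <- pk_constants
  lb_m <- k$e^2 / (4 * pi * k$eps0 * rel_permittivity * k$kB * temperature_K)
  lb_m * 1e9
}

#' Mean first-passage time for drift–diffusion across a pore
#'
#' Constant-drift diffusion on `[0, L]` with a reflecting boundary at the
#' entry (0) and an absorbing boundary at the exit (L):
#' `tau = L/v - (D/v^2) (1 - exp(-vL/D))`, evaluated through a series
#' expansion for `|vL/D| < 1e-4` so the diffusive limit `L^2/(2D)` is
#' reached stably as `v -> 0`; for strong drift it approaches the ballistic
#' limit `L/v`. This boundary choice (labelled
#' `"reflecting-absorbing"`) is the model variant used to convert residence
#' times into diffusion coefficients.
#'
#' @param v_cm_s drift velocity, cm/s (any sign; negative = drift away
#'   from the exit)
#' @param D_cm2_s diffusion coefficient, cm^2/s (> 0)
#' @param L_cm pore length, cm (> 0)
#' @return mean first-passage time in seconds
#' @export
#' @examples
#' mean_first_passage_time(0, 1e-8, 10e-7) # L^2/(2D) = 5e-5 s
mean_first_passage_time <- function(v_cm_s, D_cm2_s, L_cm) {
  stopifnot(all(D_cm2_s > 0), all(L_cm > 0))
  a <- v_cm_s * L_cm / D_cm2_s
  tau0 <- L_cm^2 / D_cm2_s
  small <- abs(a) < 1e-4
  out <- numeric(length(a))
  # series: tau = tau0 (1/2 - a/6 + a^2/24 - a^3/120)
  out[small] <- (tau0 * (0.5 - a / 6 + a^2 / 24 - a^3 / 120))[small]
  if (any(!small)) {
    v <- v_cm_s[!small] ; aa <- a[!small]
    out[!small] <- (L_cm / v) - (D_cm2_s / v^2) * (1 - exp(-aa))
  }
  out
}

#' Drift velocity of a charged analyte inside the pore
#'
#' Einstein-mobility response to the electrophoretic force, minus an
#' opposing electro-osmotic slip term:
#' `v = (D / kB T) * (z_eff e dV / l_p) - v_eo`. Positive velocities point
#' trans-to-cis (the translocation direction). The electro-osmotic term is
#' an explicit per-condition scalar (default 0), not derived from a
#' microscopic water-flux model.
#'
#' @param z_eff effective valence coupling the analyte to the field
#' @param voltage_mV applied potential, mV
#' @param pore a [pore_model()]
#' @param D_cm2_s intrapore diffusion coefficient, cm^2/s
#' @param temperature_K absolute temperature (default 295 K)
#' @param v_eo_cm_s electro-osmotic slip speed, cm/s (default 0)
#' @return drift velocity in cm/s
#' @export
drift_velocity <- function(z_eff, voltage_mV, pore = pore_model(),
                           D_cm2_s, temperature_K = 295, v_eo_cm_s = 0) {
  stopifnot(inherits(pore, "pore_model"))
  k <- pk_constants
  force_N <- z_eff * k$e * (voltage_mV * 1e-3) / (pore$length_nm * 1e-9)
  v_m_s <- (D_cm2_s * 1e-4) / (k$kB * temperature_K) * force_N
  v_m_s * 100 - v_eo_cm_s
}

#' Estimate the intrapore diffusion coefficient from residence times
#'
#' Inverts the drift–diffusion first-passage model: given residence times
#' `tau_off` over a voltage series and an effective valence from the
#' capture fit, finds the diffusion coefficient `D` for which
#' `mean_first_passage_time(drift_velocity(., D), D, l_p)` matches the
#' data in the least-squares sense. Because friction with the pore wall is
#' not modelled, the result is a lower-limit estimate of the intrapore
#' diffusivity. When the electro-osmotic term is zero the model is
#' `tau = (L^2/D) g(a)` with `a = z_eff e dV / kB T` independent of `D`,
#' and the least-squares solution is closed-form (exact on noiseless
#' forward-generated data); otherwise each voltage is solved by bisection
#' and the fit refined numerically.
#'
#' @param points tibble with `voltage_mV` and `tau_off_s` (>= 1 row)
#' @param z_eff effective valence (from [fit_kramers_rate()] or configured)
#' @param pore a [pore_model()]
#' @param temperature_K absolute temperature (default 295 K)
#' @param v_eo_cm_s electro-osmotic slip, cm/s (default 0)
#' @return object of class `diffusion_estimate`: `D_cm2_s`, `D_se`
#'   (spread of per-voltage solutions), `per_point` tibble with the
#'   per-voltage `D_i`, `model_variant`, and inputs
#' @export
estimate_diffusion <- function(points, z_eff, pore = pore_model(),
                               temperature_K = 295, v_eo_cm_s = 0) {
  pts <- as_tibble(points)
  if (!all(c("voltage_mV", "tau_off_s") %in% names(pts)) || nrow(pts) < 1) {
    abort("`points` needs `voltage_mV` and `tau_off_s` columns.",
          class = "porekin_bad_argument")
  }
  if (any(pts$tau_off_s <= 0)) {
    abort("Residence times must be positive.", class = "porekin_bad_data")
  }
  L_cm <- pore$length_nm * 1e-7
  model_tau <- function(D, V) {
    v <- drift_velocity(z_eff, V, pore, D, temperature_K, v_eo_cm_s)
    mean_first_passage_time(v, D, L_cm)
  }
  # per-voltage exact solve (bisection on log10 D); tau is monotone in D
  solve_one <- function(V, tau) {
    f <- function(lD) model_tau(10^lD, V) - tau
    lo <- -14; hi <- 0
    if (f(lo) < 0 || f(hi) > 0) {
      abort("Residence time inconsistent with any positive diffusion coefficient.",
            class = "porekin_no_bracket")
    }
    10^uniroot(f, c(lo, hi), tol = 1e-13)$root
  }
  D_i <- purrr::map2_dbl(pts$voltage_mV, pts$tau_off_s, solve_one)

  if (v_eo_cm_s == 0) {
    # tau_i = (L^2 / D) g(a_i): closed-form least squares for 1/D
    kT_mV <- thermal_voltage_mV(temperature_K)
    a <- z_eff * pts$voltage_mV / kT_mV
    g <- ifelse(abs(a) < 1e-4,
                0.5 - a / 6 + a^2 / 24 - a^3 / 120,
                1 / a - (1 - exp(-a)) / a^2)
    c_hat <- sum(g * pts$tau_off_s) / sum(g^2) # = L^2 / D
    D_hat <- L_cm^2 / c_hat
  } else {
    obj <- function(lD) sum((pts$tau_off_s - model_tau(10^lD, pts$voltage_mV))^2)
    lr <- log10(range(D_i))
    D_hat <- 10^optimize(obj, c(lr[1] - 0.5, lr[2] + 0.5), tol = 1e-12)$minimum
  }
  D_se <- if (nrow(pts) > 1) sd(D_i) / sqrt(nrow(pts)) else NA_real_
  structure(
    list(D_cm2_s = D_hat, D_se = D_se,
         per_point = tibble(voltage_mV = pts$voltage_mV,
                            tau_off_s = pts$tau_off_s, D_i = D_i),
         z_eff = z_eff, temperature_K = temperature_K,
         v_eo_cm_s = v_eo_cm_s, pore = pore,
         model_variant = "reflecting-absorbing"),
    class = "diffusion_estimate"
  )
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat("Intrapore diffusion estimate (lower limit)\n")
  cat(sprintf("  D = %.3g %s cm^2/s  [%s drift-diffusion model, %d voltages]\n",
              x$D_cm2_s,
              if (is.na(x$D_se)) "" else sprintf("+/- %.2g", x$D_se),
              x$model_variant, nrow(x$per_point)))
  invisible(x)
}

#' @export
tidy.diffusion_estimate <- function(x, ...) {
  tibble(term = "D", estimate = x$D_cm2_s, std.error = x$D_se,
         unit = "cm^2/s")
}

#' Stokes–Einstein radius / diffusion conversions
#'
#' `r = kB T / (6 pi eta D)` and its inverse, with unit handling (D in
#' cm^2/s, radius in nm, viscosity in Pa s). Used to compare intrapore
#' diffusivities with the hydrodynamic expectation for a sphere.
#'
#' @param D_cm2_s diffusion coefficient, cm^2/s
#' @param viscosity_Pa_s solvent viscosity (default 0.00089 Pa s, water)
#' @param temperature_K absolute temperature (default 295 K)
#' @return radius in nm (or diffusion coefficient in cm^2/s)
#' @export
#' @examples
#' stokes_einstein_radius(2.4e-6) # ~1 nm sphere in water
stokes_einstein_radius <- function(D_cm2_s, viscosity_Pa_s = 0.00089,
                                   temperature_K = 295) {
  stopifnot(all(D_cm2_s > 0), viscosity_Pa_s > 0, temperature_K > 0)
  k <- pk_constants
  r_m <- k$kB * temperature_K / (6 * pi * viscosity_Pa_s * D_cm2_s * 1e-4)
  r_m * 1e9
}

#' @rdname stokes_einstein_radius
#' @param radius_nm sphere radius, nm
#' @export
stokes_einstein_diffusion <- function(radius_nm, viscosity_Pa_s = 0.00089,
                                      temperature_K = 295) {
  stopifnot(all(radius_nm > 0), viscosity_Pa_s > 0, temperature_K > 0)
  k <- pk_constants
  D_m2 <- k$kB * temperature_K / (6 * pi * viscosity_Pa_s * radius_nm * 1e-9)
  D_m2 * 1e4
}

#' Excluded-volume estimate of the blockade amplitude
#'
#' Order-of-magnitude proportionality between the current drop and the
#' electrolyte volume excluded by the analyte in a cylindrical pore:
#' `dI = sigma * dV * delta / l_p^2`. Quantitative use is limited — for
#' non-cylindrical pores the blockade depends on analyte position and
#' charge — so treat this as a dimensional estimate only.
#'
#' @param sigma_S_cm buffer conductivity, S/cm
#' @param voltage_mV applied potential, mV
#' @param delta_volume_nm3 excluded volume, nm^3
#' @param pore_length_nm pore length, nm
#' @return blockade amplitude in pA
#' @export
excluded_volume_blockade <- function(sigma_S_cm, voltage_mV,
                                     delta_volume_nm3, pore_length_nm) {
  stopifnot(sigma_S_cm > 0, pore_length_nm > 0, all(delta_volume_nm3 >= 0))
  sigma_S_m <- sigma_S_cm * 100
  dI_A <- sigma_S_m * (voltage_mV * 1e-3) * (delta_volume_nm3 * 1e-27) /
    (pore_length_nm * 1e-9)^2
  dI_A * 1e12
}

#' Monte-Carlo first-passage oracle (Euler–Maruyama)
#'
#' Independent stochastic check of [mean_first_passage_time()]: simulates
#' drift–diffusion walkers on `[0, L]` with a reflecting entry and
#' absorbing exit, and returns the mean absorption time. The absorbing
#' boundary is shifted inward by the standard continuity correction
#' `0.5826 sigma sqrt(dt)` to suppress the first-order time-discretization
#' bias. Intended for validation at modest accuracy (~1–2%), not for
#' production estimation.
#'
#' @param v_cm_s,D_cm2_s,L_cm as in [mean_first_passage_time()]
#' @param n_walkers number of walkers
#' @param dt_frac time step as a fraction of `L^2/D` (default 1e-4)
#' @param max_steps safety cap on steps
#' @return mean first-passage time, s
#' @export
mc_first_passage_time <- function(v_cm_s, D_cm2_s, L_cm,
                                  n_walkers = 10000, dt_frac = 1e-4,
                                  max_steps = 5e5) {
  tau0 <- L_cm^2 / D_cm2_s
  dt <- dt_frac * tau0
  sig <- sqrt(2 * D_cm2_s * dt)
  L_eff <- L_cm - 0.5826 * sig
  x <- numeric(n_walkers)
  t_hit <- rep(NA_real_, n_walkers)
  active <- seq_len(n_walkers)
  step <- 0L
  while (length(active) > 0 && step < max_steps) {
    step <- step + 1L
    x[active] <- x[active] + v_cm_s * dt + sig * rnorm(length(active))
    x[active] <- abs(x[active]) # reflect at 0
    hit <- active[x[active] >= L_eff]
    if (length(hit)) {
      t_hit[hit] <- step * dt
      active <- setdiff(active, hit)
    }
  }
  if (length(active) > 0) {
    warn(sprintf("%d walkers not absorbed within max_steps; truncating.",
                 length(active)))
    t_hit[active] <- max_steps * dt
  }
  mean(t_hit)
}
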