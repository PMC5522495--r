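#' Reference study conditions and kinetic constants
#'
#' The three experimental conditions of the dendrimer/alpha-hemolysin
#' study with their published kinetic and energetic constants, used as
#' generator ground truth throughout the package: bimolecular rate
#' constants at +100 mV (`k_on`, 1/(s M); `k_off`, 1/s), relative blockade
#' fractions, Kramers parameters (`z_eff`, `r0` — pH 7 conditions only)
#' and intrapore diffusion coefficients (`D_cm2_s`, lower limits). These
#' printed values parameterize simulations for parameter-recovery
#' validation; they are inputs, not outputs, of the pipeline.
#'
#' @return tibble with one row per condition
#' @export
#' @examples
#' reference_conditions()
reference_conditions <- function() {
  tibble(
    label = c("pH3_1M", "pH7_1M", "pH7_0.5M"),
    pH = c(3, 7, 7),
    salt_M = c(1, 1, 0.5),
    voltage_mV = c(100, 100, 100),
    temperature_K = c(295, 295, 295),
    k_on = c(12.2e3, 15.8e3, 4.8e3),
    k_on_se = c(0.6e3, 0.8e3, 0.4e3),
    k_off = c(2.2e3, 4.4e3, 2.4e3),
    k_off_se = c(9.95, 60.3, 9.4),
    blockade_ratio = c(0.39, 0.50, 0.43),
    z_eff = c(NA, 0.49, 0.94),
    z_eff_se = c(NA, 0.03, 0.04),
    r0 = c(NA, 1.40, 0.08),
    r0_se = c(NA, 0.14, 0.01),
    D_cm2_s = c(3.04e-8, 1.78e-8, 1.12e-8)
  )
}

#' Build a pipeline run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: the condition
#' table (defaulting to [reference_conditions()]), generator settings,
#' analysis toggles and explicit seeds. Seeds are always explicit — the
#' pipeline draws no hidden entropy — so a rerun with an identical
#' configuration reproduces the outputs exactly.
#'
#' @param conditions condition tibble in the [reference_conditions()]
#'   schema (kinetic columns required for simulation-based stages)
#' @param concentrations_M analyte concentration series for the
#'   bimolecular stage, mol/L
#' @param duration_s simulated trace length per concentration, s
#' @param voltages_mV voltage series for the energetics/transport stages
#' @param n_events_voltage number of events underlying each simulated
#'   rate estimate on the voltage series
#' @param noise_sd_pA generator noise, pA RMS
#' @param sampling_rate_Hz,filter_cutoff_Hz acquisition emulation settings
#' @param seeds integer vector of seeds (one pipeline replicate per seed)
#' @param v_eo_cm_s electro-osmotic slip passed to the transport stage
#' @param out_dir optional output directory for CSV/JSON reports
#' @return list of class `porekin_config`
#' @export
porekin_config <- function(conditions = reference_conditions(),
                           concentrations_M = c(1:6) * 1e-4,
                           duration_s = 60,
                           voltages_mV = seq(50, 100, by = 10),
                           n_events_voltage = 200,
                           noise_sd_pA = 1.5,
                           sampling_rate_Hz = 80e3,
                           filter_cutoff_Hz = 10e3,
                           seeds = 1:10,
                           v_eo_cm_s = 0,
                           out_dir = NULL) {
  cfg <- list(
    conditions = as_tibble(conditions),
    concentrations_M = concentrations_M,
    duration_s = duration_s,
    voltages_mV = voltages_mV,
    n_events_voltage = n_events_voltage,
    noise_sd_pA = noise_sd_pA,
    sampling_rate_Hz = sampling_rate_Hz,
    filter_cutoff_Hz = filter_cutoff_Hz,
    seeds = as.integer(seeds),
    v_eo_cm_s = v_eo_cm_s,
    out_dir = out_dir
  )
  class(cfg) <- "porekin_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!is.data.frame(cfg$conditions) || nrow(cfg$conditions) == 0) {
    abort("Configuration has an empty condition list.",
          class = "porekin_bad_config")
  }
  need <- c("label", "pH", "salt_M", "voltage_mV", "temperature_K")
  miss <- setdiff(need, names(cfg$conditions))
  if (length(miss)) {
    abort(sprintf("Condition table lacks columns: %s.",
                  paste(miss, collapse = ", ")),
          class = "porekin_bad_config")
  }
  if (anyDuplicated(cfg$conditions$label)) {
    abort("Condition labels must be unique.", class = "porekin_bad_config")
  }
  if (length(cfg$seeds) == 0 || anyNA(cfg$seeds)) {
    abort("Seeds must be explicit integers.", class = "porekin_bad_config")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the arguments of [porekin_config()]; the
#' `conditions` entry is a list of records. Unknown keys are rejected.
#'
#' @param path YAML file path
#' @return a `porekin_config`
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(porekin_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration keys: %s.",
                  paste(unknown, collapse = ", ")),
          class = "porekin_bad_config")
  }
  if (!is.null(raw$conditions)) {
    raw$conditions <- dplyr::bind_rows(lapply(raw$conditions, as_tibble))
  }
  do.call(porekin_config, raw)
}

# simulate one trace for a condition at a given analyte concentration
sim_condition_trace <- function(cond_row, analyte_M, cfg, seed) {
  I_o <- cond_row$salt_M * cond_row$voltage_mV # 1 nS per mol/L conductance
  I_b <- I_o * (1 - cond_row$blockade_ratio)
  p <- sim_params(
    open_current_pA = I_o, blocked_current_pA = I_b,
    rate_on_true = cond_row$k_on * analyte_M,
    rate_off_true = cond_row$k_off,
    noise_sd_pA = cfg$noise_sd_pA,
    sampling_rate_Hz = cfg$sampling_rate_Hz,
    filter_cutoff_Hz = cfg$filter_cutoff_Hz,
    duration_s = cfg$duration_s, seed = seed
  )
  cond <- condition(pH = cond_row$pH, salt_M = cond_row$salt_M,
                    voltage_mV = cond_row$voltage_mV,
                    analyte_M = analyte_M,
                    temperature_K = cond_row$temperature_K,
                    label = cond_row$label)
  simulate_trace(p, cond)
}

#' Simulate capture rates over a voltage series
#'
#' Evaluates the Kramers voltage law `rate = r0 exp(z_eff e dV / kB T)` at
#' each voltage and perturbs every rate with the sampling noise of an
#' n-event exponential estimate (the rate estimate from n exponential
#' waiting times is `rate * n / Gamma(n, 1)`). This is the rate-level
#' generator used to validate the voltage-dependence fits without
#' simulating full traces.
#'
#' @param z_eff,r0 generating Kramers parameters
#' @param voltages_mV voltage series, mV
#' @param temperature_K absolute temperature, K
#' @param n_events number of events underlying each simulated estimate
#' @param seed RNG seed
#' @return tibble with `voltage_mV`, `rate_on`, `rate_se`
#' @export
simulate_voltage_rates <- function(z_eff, r0, voltages_mV, temperature_K,
                                   n_events, seed) {
  kT_mV <- thermal_voltage_mV(temperature_K)
  withr::with_seed(seed, {
    rate_true <- r0 * exp(z_eff * voltages_mV / kT_mV)
    rate_obs <- rate_true * n_events /
      rgamma(length(voltages_mV), shape = n_events, rate = 1)
    tibble(voltage_mV = voltages_mV, rate_on = rate_obs,
           rate_se = rate_obs / sqrt(n_events))
  })
}

#' Run the full analysis pipeline over a configuration
#'
#' For every condition: simulates traces across the concentration series,
#' detects events, estimates per-concentration rates (censored MLE) and
#' fits the bimolecular constants; recovers the relative blockade; where
#' Kramers ground truth is available, simulates the voltage dependence of
#' the capture rate and refits `(z_eff, r0)`; forward-generates residence
#' times from the reference diffusion coefficient and inverts the
#' first-passage model to recover `D`; and reports screening lengths and
#' net analyte charge. A selectivity block (Pitzer activities + GHK
#' round trip at the anion-selective anchors) is computed once. When
#' `out_dir` is set, per-condition event/rate CSVs, fit JSONs and a
#' manifest (package version, configuration hash, seeds) are written.
#'
#' @param cfg a `porekin_config` (or a YAML path accepted by
#'   [read_config()])
#' @return list of class `porekin_run`: `summary` (one row per condition),
#'   `rates` (per condition x concentration x seed), `kinetic_fits`,
#'   `kramers_fits`, `diffusion`, `selectivity`, `manifest`
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  conds <- cfg$conditions
  charge_mod <- pamam_g1_charge_model()

  per_cond <- purrr::map(seq_len(nrow(conds)), function(i) {
    row <- conds[i, ]
    res <- list(label = row$label)

    if (all(c("k_on", "k_off", "blockade_ratio") %in% names(row)) &&
        !anyNA(row[c("k_on", "k_off", "blockade_ratio")])) {
      rate_rows <- purrr::map(cfg$seeds, function(sd) {
        purrr::map(cfg$concentrations_M, function(cc) {
          tr <- sim_condition_trace(row, cc, cfg, seed = sd)
          ev <- detect_events(tr)
          rp <- rates_from_events(ev)
          rp$seed <- sd
          blk <- relative_blockade(ev)
          rp$blockade_ratio <- blk$ratio
          rp
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
      fits <- rate_rows |>
        dplyr::group_by(.data$seed) |>
        dplyr::group_map(~ fit_bimolecular(.x))
      res$rates <- rate_rows
      res$kinetic_fit <- tibble(
        label = row$label,
        k_on = median(purrr::map_dbl(fits, "k_on")),
        k_off = median(purrr::map_dbl(fits, "k_off")),
        n_seeds = length(fits)
      )
      res$blockade <- tibble(label = row$label,
                             blockade_ratio = mean(rate_rows$blockade_ratio))
    }

    if (all(c("z_eff", "r0") %in% names(row)) && !anyNA(row[c("z_eff", "r0")])) {
      kfits <- purrr::map(cfg$seeds, function(sd) {
        pts <- simulate_voltage_rates(row$z_eff, row$r0, cfg$voltages_mV,
                                      row$temperature_K,
                                      cfg$n_events_voltage, seed = sd)
        fit_kramers_rate(pts, temperature_K = row$temperature_K)
      })
      res$kramers <- tibble(
        label = row$label,
        z_eff = median(purrr::map_dbl(kfits, "z_eff")),
        r0 = median(purrr::map_dbl(kfits, "r0")),
        z_eff_se = median(purrr::map_dbl(kfits, "z_eff_se")),
        r0_se = median(purrr::map_dbl(kfits, "r0_se"))
      )
    }

    if ("D_cm2_s" %in% names(row) && !is.na(row$D_cm2_s) &&
        "z_eff" %in% names(row) && !is.na(row$z_eff)) {
      pore <- pore_model()
      L_cm <- pore$length_nm * 1e-7
      tau_fwd <- purrr::map_dbl(cfg$voltages_mV, function(V) {
        v <- drift_velocity(row$z_eff, V, pore, row$D_cm2_s,
                            row$temperature_K, cfg$v_eo_cm_s)
        mean_first_passage_time(v, row$D_cm2_s, L_cm)
      })
      dest <- estimate_diffusion(
        tibble(voltage_mV = cfg$voltages_mV, tau_off_s = tau_fwd),
        z_eff = row$z_eff, pore = pore,
        temperature_K = row$temperature_K, v_eo_cm_s = cfg$v_eo_cm_s
      )
      res$diffusion <- tibble(label = row$label, D_est = dest$D_cm2_s,
                              model_variant = dest$model_variant)
    }

    res$physics <- tibble(
      label = row$label,
      net_charge = as.numeric(net_charge(charge_mod, row$pH)),
      debye_nm = debye_length(row$salt_M, 300),
      bjerrum_nm = bjerrum_length(300)
    )
    res
  })

  sel <- dplyr::bind_rows(
    selectivity_report(
      psi_rev_mV = ghk_reversal_potential(0.453, salt_activities(0.1, 3))
    ) |> mutate(pH = 3, .before = 1),
    selectivity_report(
      psi_rev_mV = ghk_reversal_potential(0.703, salt_activities(0.1, 3))
    ) |> mutate(pH = 7, .before = 1)
  )

  pick <- function(name) {
    dplyr::bind_rows(purrr::compact(purrr::map(per_cond, name)))
  }
  kin <- pick("kinetic_fit"); blk <- pick("blockade")
  kra <- pick("kramers"); dif <- pick("diffusion"); phy <- pick("physics")
  summary <- conds["label"]
  for (tb in list(blk, kin, kra, dif, phy)) {
    if (nrow(tb)) summary <- dplyr::left_join(summary, tb, by = "label")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("porekin")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    seeds = cfg$seeds,
    timestamp = NULL # deliberately unset: outputs must be rerun-identical
  )

  out <- structure(
    list(summary = summary, rates = pick("rates"),
         kinetic_fits = kin, kramers_fits = kra, diffusion = dif,
         selectivity = sel, physics = phy, manifest = manifest),
    class = "porekin_run"
  )
  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$summary, file.path(dir, "summary.csv"))
  if (nrow(run$rates)) {
    readr::write_csv(run$rates, file.path(dir, "rates.csv"))
  }
  readr::write_csv(run$selectivity, file.path(dir, "selectivity.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(kinetics = run$kinetic_fits, kramers = run$kramers_fits,
         diffusion = run$diffusion, physics = run$physics),
    file.path(dir, "fits.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.porekin_run <- function(x, ...) {
  cat("porekin pipeline run\n")
  print(x$summary)
  invisible(x)
}
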