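#' Van't Hoff–Arrhenius fit of capture times vs voltage
#'
#' Fits `tau_on = a * exp(-dV / b)`: an exponentially voltage-accelerated
#' capture time, the signature of a barrier-limited entry process. The fit
#' is nonlinear least squares seeded by the log-linear regression (to which
#' it is equivalent for multiplicative noise).
#'
#' @param points tibble with `voltage_mV` and `tau_on_s` (>= 3 voltages,
#'   all times positive)
#' @return object of class `arrhenius_fit` with `a` (s), `b` (mV), their
#'   standard errors and covariance
#' @export
#' @examples
#' v <- c(50, 75, 100)
#' fit_arrhenius_tau(tibble::tibble(voltage_mV = v, tau_on_s = exp(-v / 25)))
fit_arrhenius_tau <- function(points) {
  pts <- as_tibble(points)
  if (!all(c("voltage_mV", "tau_on_s") %in% names(pts))) {
    abort("`points` needs `voltage_mV` and `tau_on_s` columns.",
          class = "porekin_bad_argument")
  }
  if (nrow(pts) < 3) {
    abort("Need at least 3 voltages.", class = "porekin_bad_argument")
  }
  if (any(pts$tau_on_s <= 0)) {
    abort("Capture times must be positive.", class = "porekin_bad_data")
  }
  lin <- lm(log(tau_on_s) ~ voltage_mV, data = pts)
  b0 <- -1 / unname(coef(lin)[2])
  a0 <- exp(unname(coef(lin)[1]))
  # nls cannot iterate from an exact (zero-residual) start; fall back to the
  # log-linear estimates with delta-method errors in that case
  fit <- tryCatch(
    nls(tau_on_s ~ a * exp(-voltage_mV / b), data = pts,
        start = list(a = a0, b = b0)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    est <- coef(fit)
    se <- sqrt(diag(quiet_vcov(fit)))
    out <- list(a = unname(est["a"]), b = unname(est["b"]),
                a_se = unname(se["a"]), b_se = unname(se["b"]),
                cov = quiet_vcov(fit), points = pts)
  } else {
    V <- quiet_vcov(lin)
    s <- unname(coef(lin)[2])
    out <- list(a = a0, b = b0,
                a_se = a0 * sqrt(V[1, 1]), b_se = sqrt(V[2, 2]) / s^2,
                cov = V, points = pts)
  }
  structure(out, class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("van't Hoff-Arrhenius fit: tau_on = a * exp(-dV/b)\n")
  cat(sprintf("  a = %.4g +/- %.2g s\n  b = %.4g +/- %.2g mV\n",
              x$a, x$a_se, x$b, x$b_se))
  invisible(x)
}

#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b),
         std.error = c(x$a_se, x$b_se), unit = c("s", "mV"))
}

#' Kramers-form fit of capture rate vs voltage
#'
#' Fits `ln rate_on = ln r0 + z_eff * e * dV / (kB * T)` by (optionally
#' weighted) linear regression in log space, matching the multiplicative
#' error structure of rate estimates. Returns the zero-voltage capture rate
#' `r0` and the effective valence `z_eff` (slope times the thermal voltage,
#' 25.4 mV at 295 K). The prefactor and barrier height are not separately
#' identifiable — only their product `r0 = A * exp(-U*/kBT)` is estimated,
#' so neither is reported alone.
#'
#' @param points tibble with `voltage_mV`, `rate_on` (1/s) and optionally
#'   `rate_se` (standard error of the rate, used for weights)
#' @param temperature_K absolute temperature (default 295 K)
#' @return object of class `kramers_fit` with `r0`, `r0_se` (1/s), `z_eff`,
#'   `z_eff_se`, `temperature_K` and the log-space covariance
#' @export
fit_kramers_rate <- function(points, temperature_K = 295) {
  pts <- as_tibble(points)
  if (!all(c("voltage_mV", "rate_on") %in% names(pts))) {
    abort("`points` needs `voltage_mV` and `rate_on` columns.",
          class = "porekin_bad_argument")
  }
  if (nrow(pts) < 3) {
    abort("Need at least 3 voltages.", class = "porekin_bad_argument")
  }
  if (any(pts$rate_on <= 0)) {
    abort("Rates must be positive.", class = "porekin_bad_data")
  }
  assert_positive_scalar(temperature_K, "temperature_K")
  kT_mV <- thermal_voltage_mV(temperature_K)
  w <- if ("rate_se" %in% names(pts)) {
    # sd of log(rate) ~ relative SE of rate
    1 / pmax(pts$rate_se / pts$rate_on, .Machine$double.eps)^2
  } else rep(1, nrow(pts))
  fit <- lm(log(rate_on) ~ voltage_mV, data = pts, weights = w)
  slope <- unname(coef(fit)[2])
  inter <- unname(coef(fit)[1])
  V <- quiet_vcov(fit)
  r0 <- exp(inter)
  structure(
    list(r0 = r0, r0_se = r0 * sqrt(V[1, 1]),
         z_eff = slope * kT_mV, z_eff_se = sqrt(V[2, 2]) * kT_mV,
         temperature_K = temperature_K, cov_log = V, points = pts),
    class = "kramers_fit"
  )
}

#' @export
print.kramers_fit <- function(x, ...) {
  cat("Kramers capture fit: rate_on = r0 * exp(z_eff e dV / kB T)\n")
  cat(sprintf("  z_eff = %.3g +/- %.2g\n  r0    = %.3g +/- %.2g 1/s  (T = %g K)\n",
              x$z_eff, x$z_eff_se, x$r0, x$r0_se, x$temperature_K))
  invisible(x)
}

#' @export
tidy.kramers_fit <- function(x, ...) {
  tibble(term = c("z_eff", "r0"), estimate = c(x$z_eff, x$r0),
         std.error = c(x$z_eff_se, x$r0_se), unit = c("", "1/s"))
}

#' @export
glance.kramers_fit <- function(x, ...) {
  tibble(z_eff = x$z_eff, r0 = x$r0, temperature_K = x$temperature_K,
         n_points = nrow(x$points))
}

#' @export
autoplot.kramers_fit <- function(object, ...) {
  pts <- object$points
  kT_mV <- thermal_voltage_mV(object$temperature_K)
  grid <- tibble(voltage_mV = seq(min(pts$voltage_mV), max(pts$voltage_mV),
                                  length.out = 100))
  grid$rate_on <- object$r0 * exp(object$z_eff * grid$voltage_mV / kT_mV)
  ggplot(pts, aes(x = .data$voltage_mV, y = .data$rate_on)) +
    geom_point() +
    geom_line(data = grid, colour = "grey40") +
    scale_y_log10() +
    labs(x = "voltage (mV)", y = "capture rate (1/s)") +
    theme_minimal()
}

#' Qualitative voltage signature of the escape pathway
#'
#' Residence times that shorten with increasing voltage indicate
#' translocation (the analyte exits down-field on the far side); residence
#' times that lengthen indicate retreat against the field back to the entry
#' side, the behaviour of analytes too large to pass the constriction.
#' Classified from the sign of the log-residence-time slope vs voltage.
#'
#' @param points tibble with `voltage_mV` and `tau_off_s`
#' @return `"translocation"` or `"return-to-trans"` (qualitative only)
#' @export
escape_voltage_signature <- function(points) {
  pts <- as_tibble(points)
  if (!all(c("voltage_mV", "tau_off_s") %in% names(pts)) || nrow(pts) < 2) {
    abort("`points` needs >= 2 rows with `voltage_mV` and `tau_off_s`.",
          class = "porekin_bad_argument")
  }
  slope <- coef(lm(log(tau_off_s) ~ voltage_mV, data = pts))[2]
  if (slope < 0) "translocation" else "return-to-trans"
}

#' Free-energy barrier difference between two conditions
#'
#' `dU* = kB T ln(r0_A / r0_B)`, the difference in the entry barrier
#' between two conditions sharing the same Kramers prefactor (equal analyte
#' concentration and bulk diffusivity). Reported in kcal/mol and in kBT
#' units; antisymmetric under swapping the conditions.
#'
#' @param r0_A,r0_B zero-voltage capture rates, 1/s
#' @param temperature_K absolute temperature (default 295 K)
#' @param labels length-2 character vector naming the conditions
#' @return object of class `barrier_delta` with `delta_kcal_mol`,
#'   `delta_kBT`, `labels`, `temperature_K`
#' @export
#' @examples
#' barrier_difference(1.40, 0.08) # ~1.68 kcal/mol
barrier_difference <- function(r0_A, r0_B, temperature_K = 295,
                               labels = c("A", "B")) {
  assert_positive_scalar(r0_A, "r0_A")
  assert_positive_scalar(r0_B, "r0_B")
  assert_positive_scalar(temperature_K, "temperature_K")
  delta_kBT <- log(r0_A / r0_B)
  structure(
    list(delta_kcal_mol = kBT_kcal_mol(temperature_K) * delta_kBT,
         delta_kBT = delta_kBT, labels = labels,
         temperature_K = temperature_K),
    class = "barrier_delta"
  )
}

#' @export
print.barrier_delta <- function(x, ...) {
  cat(sprintf("Barrier difference U*(%s) - U*(%s): %.3f kcal/mol (%.3f kBT) at %g K\n",
              x$labels[2], x$labels[1], x$delta_kcal_mol, x$delta_kBT,
              x$temperature_K))
  invisible(x)
}
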