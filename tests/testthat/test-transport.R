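test_that("protonation model reproduces the accepted dendrimer charge states", {
  m <- pamam_g1_charge_model()
  expect_equal(sum(m$count), 14) # 8 primary + 6 tertiary amines
  q <- net_charge(m, c(3, 7, 10.3))
  expect_lt(abs(q[1] - 12), 0.5)
  expect_lt(abs(q[2] - 8), 0.5)
  expect_lt(q[3], 1)
  expect_equal(attr(q, "nearest"), c(12, 8, 0))
  expect_error(net_charge(m, 15), class = "porekin_bad_argument")
})

test_that("Debye length matches known values and its scaling law", {
  expect_equal(debye_length(1, 300, 78), 0.30, tolerance = 0.02)
  expect_equal(debye_length(0.5, 300, 78), 0.43, tolerance = 0.02)
  # quadrupling ionic strength halves the screening length exactly
  expect_equal(debye_length(4 * 0.37), debye_length(0.37) / 2,
               tolerance = 1e-12)
})

test_that("Bjerrum length is ~0.7 nm in water and obeys its identities", {
  lB <- bjerrum_length(300, 78)
  expect_equal(lB, 0.70, tolerance = 0.03)
  expect_equal(bjerrum_length(300, 156), lB / 2, tolerance = 1e-12)
  # kappa^2 = 8 pi lB NA I (algebraic identity with the Debye length)
  I <- 0.8
  kappa2_m2 <- 8 * pi * (lB * 1e-9) * pk_constants$NA_avogadro * I * 1e3
  expect_equal(1 / sqrt(kappa2_m2) * 1e9, debye_length(I, 300, 78),
               tolerance = 1e-9)
})

test_that("mean first-passage time has correct limits and closed-form values", {
  # diffusive limit L^2 / 2D
  expect_equal(mean_first_passage_time(0, 1e-8, 10e-7), 5e-5,
               tolerance = 1e-12)
  # closed form at vL/D = 1
  expect_equal(mean_first_passage_time(0.01, 1e-8, 1e-6), 3.678794e-5,
               tolerance = 1e-6)
  # strong-drift behaviour: tau = (L/v)(1 - (1 - exp(-a))/a), approaching
  # the ballistic limit L/v (within 1% by vL/D = 100)
  v10 <- 10 * 1e-8 / 1e-6
  expect_equal(mean_first_passage_time(v10, 1e-8, 1e-6),
               (1e-6 / v10) * (1 - (1 - exp(-10)) / 10), tolerance = 1e-12)
  v100 <- 100 * 1e-8 / 1e-6
  expect_lt(abs(mean_first_passage_time(v100, 1e-8, 1e-6) - 1e-6 / v100) /
              (1e-6 / v100), 0.01)
  # series branch joins the direct formula smoothly across |vL/D| = 1e-4
  expect_equal(mean_first_passage_time(9e-7, 1e-8, 1e-6),
               mean_first_passage_time(1.1e-6, 1e-8, 1e-6),
               tolerance = 1e-4)
})

test_that("closed-form MFPT agrees with a Monte-Carlo first-passage oracle", {
  D <- 1e-8; L <- 1e-6
  for (a in c(0, 1, 5)) {
    v <- a * D / L
    mc <- withr::with_seed(30 + a, mc_first_passage_time(
      v, D, L, n_walkers = 6000, dt_frac = 1e-4))
    cf <- mean_first_passage_time(v, D, L)
    expect_lt(abs(mc - cf) / cf, 0.02)
  }
})

test_that("drift velocity is linear in voltage and zero without forcing", {
  pore <- pore_model()
  expect_equal(drift_velocity(0.5, 0, pore, 1e-8, 295, 0), 0)
  v1 <- drift_velocity(0.49, 50, pore, 1.78e-8, 295, 0)
  v2 <- drift_velocity(0.49, 100, pore, 1.78e-8, 295, 0)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  # direct formula evaluation oracle
  k <- pk_constants
  expected <- (1.78e-8 * 1e-4 / (k$kB * 295)) *
    (0.49 * k$e * 0.1 / (10e-9)) * 100
  expect_equal(drift_velocity(0.49, 100, pore, 1.78e-8, 295, 0), expected,
               tolerance = 1e-12)
  # electro-osmotic slip subtracts directly
  expect_equal(drift_velocity(0.49, 100, pore, 1.78e-8, 295, 0.001),
               expected - 0.001, tolerance = 1e-12)
})

test_that("diffusion estimation inverts forward-generated residence times exactly", {
  pore <- pore_model()
  L_cm <- pore$length_nm * 1e-7
  v_mV <- seq(50, 100, by = 10)
  forward_tau <- function(D, z, v_eo = 0) {
    vapply(v_mV, function(V) {
      v <- drift_velocity(z, V, pore, D, 295, v_eo)
      mean_first_passage_time(v, D, L_cm)
    }, numeric(1))
  }
  for (D_true in c(3.04e-8, 1.78e-8, 1.12e-8)) {
    tau <- forward_tau(D_true, 0.49)
    est <- estimate_diffusion(tibble::tibble(voltage_mV = v_mV,
                                             tau_off_s = tau),
                              z_eff = 0.49, pore = pore)
    expect_equal(est$D_cm2_s, D_true, tolerance = 1e-4)
  }
  # with a non-zero electro-osmotic term (numerical solver path)
  tau <- forward_tau(1.78e-8, 0.49, v_eo = 0.002)
  est <- estimate_diffusion(tibble::tibble(voltage_mV = v_mV, tau_off_s = tau),
                            z_eff = 0.49, pore = pore, v_eo_cm_s = 0.002)
  expect_equal(est$D_cm2_s, 1.78e-8, tolerance = 1e-4)

  # doubling all residence times halves the drift-free-form solution exactly
  tau <- forward_tau(2e-8, 0.49)
  est1 <- estimate_diffusion(tibble::tibble(voltage_mV = v_mV,
                                            tau_off_s = tau), 0.49, pore)
  est2 <- estimate_diffusion(tibble::tibble(voltage_mV = v_mV,
                                            tau_off_s = 2 * tau), 0.49, pore)
  expect_equal(est2$D_cm2_s, est1$D_cm2_s / 2, tolerance = 1e-10)

  # single-voltage bisection path agrees with the least-squares path
  one <- estimate_diffusion(tibble::tibble(voltage_mV = 100,
                                           tau_off_s = tau[6]), 0.49, pore)
  expect_equal(one$D_cm2_s, 2e-8, tolerance = 1e-4)
  expect_equal(one$per_point$D_i, one$D_cm2_s, tolerance = 1e-6)

  # impossible residence time -> diagnostic error
  expect_error(
    estimate_diffusion(tibble::tibble(voltage_mV = 100, tau_off_s = 1e9),
                       0.49, pore),
    class = "porekin_no_bracket"
  )
})

test_that("diffusion recovery tolerates multiplicative noise on residence times", {
  pore <- pore_model()
  L_cm <- pore$length_nm * 1e-7
  v_mV <- seq(50, 100, by = 10)
  D_true <- 1.78e-8
  tau0 <- vapply(v_mV, function(V) {
    v <- drift_velocity(0.49, V, pore, D_true, 295, 0)
    mean_first_passage_time(v, D_true, L_cm)
  }, numeric(1))
  D_hat <- withr::with_seed(31, vapply(1:50, function(i) {
    tau <- tau0 * exp(rnorm(length(tau0), sd = 0.1))
    estimate_diffusion(tibble::tibble(voltage_mV = v_mV, tau_off_s = tau),
                       0.49, pore)$D_cm2_s
  }, numeric(1)))
  expect_lt(abs(median(D_hat) - D_true) / D_true, 0.15)
})

test_that("inversion preserves the ordering of the study's diffusion coefficients", {
  pore <- pore_model()
  L_cm <- pore$length_nm * 1e-7
  v_mV <- seq(50, 100, by = 10)
  cases <- list(pH3_1M = list(D = 3.04e-8, z = 0.49),
                pH7_1M = list(D = 1.78e-8, z = 0.49),
                pH7_0.5M = list(D = 1.12e-8, z = 0.94))
  D_rec <- vapply(cases, function(cs) {
    tau <- vapply(v_mV, function(V) {
      v <- drift_velocity(cs$z, V, pore, cs$D, 295, 0)
      mean_first_passage_time(v, cs$D, L_cm)
    }, numeric(1))
    estimate_diffusion(tibble::tibble(voltage_mV = v_mV, tau_off_s = tau),
                       cs$z, pore)$D_cm2_s
  }, numeric(1))
  expect_gt(D_rec["pH3_1M"], D_rec["pH7_1M"])
  expect_gt(D_rec["pH7_1M"], D_rec["pH7_0.5M"])
})

test_that("Stokes-Einstein conversions are exact inverses with correct magnitude", {
  D <- stokes_einstein_diffusion(1, 0.00089, 295)
  expect_equal(D, 2.4e-6, tolerance = 0.02)
  expect_equal(stokes_einstein_radius(D, 0.00089, 295), 1, tolerance = 1e-12)
  expect_equal(stokes_einstein_radius(D / 2, 0.00089, 295), 2,
               tolerance = 1e-12)
})

test_that("excluded-volume blockade is proportional and dimensionally consistent", {
  expect_equal(excluded_volume_blockade(0.112, 100, 0, 10), 0)
  b1 <- excluded_volume_blockade(0.112, 50, 3, 10)
  expect_equal(excluded_volume_blockade(0.112, 100, 3, 10), 2 * b1,
               tolerance = 1e-12)
  expect_equal(excluded_volume_blockade(0.112, 50, 6, 10), 2 * b1,
               tolerance = 1e-12)
  # independent SI dimensional-analysis oracle
  sigma_SI <- 0.112 * 1e2            # S/m
  dV_SI <- 100e-3                    # V
  delta_SI <- 3 * (1e-9)^3           # m^3
  lp_SI <- 10e-9                     # m
  expected_pA <- sigma_SI * dV_SI * delta_SI / lp_SI^2 * 1e12
  expect_equal(excluded_volume_blockade(0.112, 100, 3, 10), expected_pA,
               tolerance = 1e-12)
})
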