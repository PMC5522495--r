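test_that("all-points histogram covers the data and conserves sample counts", {
  tr <- square_trace(c(0.001, 0.004), c(0.001, 0.001), fs = 1e4,
                     duration_s = 0.01)
  h <- all_points_histogram(tr, bin_width_pA = 0.25)
  expect_s3_class(h, "pore_histogram")
  expect_equal(sum(h$count), nrow(tr))
  expect_length(unique(h$current_pA[h$count > 0]), 2) # noiseless two-level

  expect_error(all_points_histogram(tr, bin_width_pA = 0),
               class = "porekin_bad_argument")
})

test_that("histogram mode sits on the underlying level under Gaussian noise", {
  x <- withr::with_seed(1, rnorm(2e5, mean = 100, sd = 1))
  h <- all_points_histogram(pore_trace(x, 1e4), bin_width_pA = 0.25)
  mode_pA <- h$current_pA[which.max(h$count)]
  expect_lt(abs(mode_pA - 100), 0.5)
})

test_that("occupied-bin mass reflects state occupancy", {
  p <- sim_params(100, 50, rate_on_true = 50, rate_off_true = 50,
                  noise_sd_pA = 0, filter_cutoff_Hz = NA,
                  sampling_rate_Hz = 2e4, duration_s = 40, seed = 9)
  tr <- simulate_trace(p)
  h <- all_points_histogram(tr, bin_width_pA = 0.5)
  frac_blocked <- sum(h$count[abs(h$current_pA - 50) < 2]) / sum(h$count)
  truth <- trace_truth(tr)
  occ <- sum((truth$end_s - truth$start_s)[truth$state == "blocked"]) /
    max(truth$end_s)
  expect_lt(abs(frac_blocked - occ), 0.02)
})

test_that("level detection finds the open and blocked modes", {
  tr <- square_trace(seq(0.002, 0.08, by = 0.008), rep(0.004, 10),
                     open = 100, blocked = 50, fs = 2e4, duration_s = 0.09)
  lv <- detect_levels(all_points_histogram(tr))
  expect_equal(unname(lv["open"]), 100, tolerance = 1e-6)
  expect_equal(unname(lv["blocked"]), 50, tolerance = 1e-6)

  # noisy generator fixture: recovered levels within 1 pA of the settings
  p <- sim_params(100, 50, rate_on_true = 40, rate_off_true = 120,
                  noise_sd_pA = 1.5, filter_cutoff_Hz = 10e3,
                  sampling_rate_Hz = 80e3, duration_s = 5, seed = 21)
  lv2 <- detect_levels(all_points_histogram(simulate_trace(p)))
  expect_lt(abs(lv2["open"] - 100), 1)
  expect_lt(abs(lv2["blocked"] - 50), 1)
})

test_that("unimodal histograms raise a no-blockade condition distinct from I/O errors", {
  x <- withr::with_seed(2, rnorm(5e4, 100, 1))
  h <- all_points_histogram(pore_trace(x, 1e4))
  expect_error(detect_levels(h), class = "porekin_no_blockades")
})

test_that("three-level traces follow the documented top-two / error contract", {
  x <- c(rep(100, 5e4), rep(70, 2e4), rep(40, 4e4))
  h <- all_points_histogram(pore_trace(x, 1e4))
  expect_error(detect_levels(h, top_two = FALSE),
               class = "porekin_multimodal")
  lv <- detect_levels(h, top_two = TRUE)
  expect_equal(sort(unname(lv)), c(40, 100), tolerance = 1e-6)
})

test_that("square events are recovered with exact counts and dwell times", {
  starts <- seq(0.01, 0.1, by = 0.01)
  tr <- square_trace(starts, rep(0.001, 10), fs = 80e3, duration_s = 0.115)
  ev <- detect_events(tr, levels = c(open = 100, blocked = 50))
  expect_equal(nrow(ev), 10)
  expect_true(all(abs(ev$dwell_s - 0.001) <= 1.5 / 80e3))
  expect_equal(relative_blockade(ev)$ratio, 0.5, tolerance = 1e-6)

  # ordering invariants
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(ev$tau_on_s[-1] > 0))
  expect_equal(ev$tau_on_s[-1], ev$start_s[-1] - ev$end_s[-10])
})

test_that("events shorter than the minimum duration are censored, not returned", {
  tr <- square_trace(0.01, 0.0005, fs = 80e3, duration_s = 0.03)
  ev <- detect_events(tr, levels = c(open = 100, blocked = 50),
                      min_duration_s = 0.001)
  expect_equal(nrow(ev), 0)
  expect_equal(censor_floor(ev), 0.001)
})

test_that("a constant offset shifts amplitudes but leaves dwell times unchanged", {
  starts <- seq(0.01, 0.06, by = 0.01)
  durs <- c(0.001, 0.002, 0.0015, 0.001, 0.003, 0.002)
  tr <- square_trace(starts, durs, fs = 80e3, duration_s = 0.07)
  tr_off <- pore_trace(tr$current_pA + 10, 80e3)
  ev <- detect_events(tr, levels = c(open = 100, blocked = 50))
  ev_off <- detect_events(tr_off, levels = c(open = 110, blocked = 60))
  expect_equal(ev$dwell_s, ev_off$dwell_s)
  expect_equal(ev$dI_pA, ev_off$dI_pA, tolerance = 1e-9)
})

test_that("poorly separated levels are refused", {
  x <- withr::with_seed(3, rnorm(5e4, 100, 3))
  tr <- pore_trace(x, 1e4)
  expect_error(detect_events(tr, levels = c(open = 100, blocked = 95)),
               class = "porekin_insufficient_separation")
})

test_that("relative blockade is unit-scale invariant and refuses empty tables", {
  starts <- seq(0.01, 0.05, by = 0.01)
  tr <- square_trace(starts, rep(0.002, 5), open = 100, blocked = 57)
  ev <- detect_events(tr, levels = c(open = 100, blocked = 57))
  r1 <- relative_blockade(ev)$ratio
  tr2 <- pore_trace(tr$current_pA * 3, 80e3)
  ev2 <- detect_events(tr2, levels = c(open = 300, blocked = 171))
  expect_equal(relative_blockade(ev2)$ratio, r1, tolerance = 1e-9)

  empty <- detect_events(square_trace(0.01, 0.0005, duration_s = 0.03),
                         levels = c(open = 100, blocked = 50),
                         min_duration_s = 0.001)
  expect_error(relative_blockade(empty), class = "porekin_empty_events")
})

test_that("blockade fraction is voltage independent when the generator makes it so", {
  fraction <- 0.43
  voltages <- c(50, 75, 100)
  ratios <- vapply(voltages, function(V) {
    I_o <- 0.5 * V # 0.5 nS in 0.5 M KCl
    p <- sim_params(I_o, I_o * (1 - fraction), rate_on_true = 25,
                    rate_off_true = 2400, noise_sd_pA = 1.5,
                    sampling_rate_Hz = 80e3, filter_cutoff_Hz = 10e3,
                    duration_s = 10, seed = 100 + V)
    ev <- detect_events(simulate_trace(p))
    relative_blockade(ev)$ratio
  }, numeric(1))
  fit <- lm(ratios ~ voltages)
  slope_se <- sqrt(vcov(fit)[2, 2])
  expect_lt(abs(coef(fit)[2]), 2 * slope_se + 1e-6)
  expect_lt(abs(mean(ratios) - fraction), 0.01)
})

test_that("event tables export to CSV with a JSON sidecar", {
  tr <- square_trace(seq(0.01, 0.05, by = 0.01), rep(0.002, 5))
  ev <- detect_events(tr, levels = c(open = 100, blocked = 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("start_s", "end_s", "dwell_s", "tau_on_s",
                              "dI_pA"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$open_level_pA, 100)
})
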