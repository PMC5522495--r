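test_that("noiseless generator produces two exact levels with exponential dwells", {
  p <- sim_params(100, 50, rate_on_true = 10, rate_off_true = 10,
                  noise_sd_pA = 0, filter_cutoff_Hz = NA,
                  sampling_rate_Hz = 1e4, duration_s = 10, seed = 42)
  tr <- simulate_trace(p)
  expect_setequal(unique(tr$current_pA), c(100, 50))
  expect_equal(nrow(tr), 1e5)

  truth <- trace_truth(tr)
  # interval tiling of [0, duration]
  expect_equal(truth$start_s[1], 0)
  expect_equal(truth$end_s[nrow(truth)], 10)
  expect_equal(truth$start_s[-1], truth$end_s[-nrow(truth)])

  open_d <- with(truth[-nrow(truth), ], (end_s - start_s)[state == "open"])
  se <- 0.1 / sqrt(length(open_d))
  expect_lt(abs(mean(open_d) - 0.1), 2 * se)
})

test_that("event counts follow the renewal-process expectation", {
  # capture rate from the acidic / 1 M condition at 500 uM
  row <- ref[ref$label == "pH3_1M", ]
  r_on <- row$k_on * 500e-6
  p <- sim_params(100, 61, rate_on_true = r_on, rate_off_true = row$k_off,
                  noise_sd_pA = 0, filter_cutoff_Hz = NA,
                  sampling_rate_Hz = 2e4, duration_s = 60, seed = 11)
  tr <- simulate_trace(p)
  n_blocked <- sum(trace_truth(tr)$state == "blocked")
  expected <- r_on * 60
  expect_lt(abs(n_blocked - expected), 3 * sqrt(expected))
})

test_that("dwell durations are exponential with the generating rate across seeds", {
  rate <- 200
  pass <- vapply(1:100, function(sd) {
    p <- sim_params(100, 50, rate_on_true = rate, rate_off_true = rate,
                    noise_sd_pA = 0, filter_cutoff_Hz = NA,
                    sampling_rate_Hz = 5e3, duration_s = 5.2, seed = sd)
    truth <- trace_truth(simulate_trace(p))
    truth <- truth[-nrow(truth), ] # last interval truncated by trace end
    d <- with(truth, (end_s - start_s)[state == "blocked"])
    stats::ks.test(d, "pexp", rate)$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("identical parameters and seed give identical traces", {
  p <- sim_params(100, 50, 20, 500, duration_s = 2, sampling_rate_Hz = 2e4,
                  filter_cutoff_Hz = 5e3, seed = 7)
  t1 <- simulate_trace(p)
  t2 <- simulate_trace(p)
  expect_identical(t1$current_pA, t2$current_pA)
  expect_identical(trace_truth(t1), trace_truth(t2))
  p2 <- sim_params(100, 50, 20, 500, duration_s = 2, sampling_rate_Hz = 2e4,
                   filter_cutoff_Hz = 5e3, seed = 8)
  expect_false(identical(simulate_trace(p2)$current_pA, t1$current_pA))
})

test_that("invalid generator settings are rejected with the offending field named", {
  expect_error(sim_params(100, 50, -1, 10), "rate_on_true",
               class = "porekin_bad_sim_params")
  expect_error(sim_params(100, 50, 10, 10, duration_s = 0), "duration_s",
               class = "porekin_bad_sim_params")
  expect_error(sim_params(100, 50, 10, 10, sampling_rate_Hz = -5),
               "sampling_rate_Hz", class = "porekin_bad_sim_params")
  expect_error(sim_params(50, 100, 10, 10), class = "porekin_bad_sim_params")
  expect_error(sim_params(100, 50, 10, 10, sampling_rate_Hz = 1e4,
                          filter_cutoff_Hz = 8e3),
               class = "porekin_bad_sim_params")
})

test_that("low-pass filter has unit DC gain, ~0.34/fc rise time and preserves plateaus", {
  fs <- 80e3
  # constant trace unchanged
  const <- pore_trace(rep(80, 1000), fs)
  expect_equal(apply_lowpass(const, 10e3)$current_pA, rep(80, 1000),
               tolerance = 1e-12)

  # step 100 -> 50 pA: 10-90% rise time about 34 us at 10 kHz
  step <- pore_trace(c(rep(100, 4000), rep(50, 4000)), fs)
  f <- apply_lowpass(step, 10e3)
  expect_equal(nrow(f), 8000)
  y <- f$current_pA
  t <- f$time_s
  t_at <- function(level) {
    i <- which(y <= level)[1]
    t[i - 1] + (t[i] - t[i - 1]) * (y[i - 1] - level) / (y[i - 1] - y[i])
  }
  rise <- t_at(50 + 0.1 * 50) - t_at(50 + 0.9 * 50)
  expect_lt(abs(rise - 34e-6), 0.2 * 34e-6)

  # 1 ms square pulse >> rise time: plateau within 1% of full depth
  pulse <- square_trace(0.005, 0.001, open = 100, blocked = 50, fs = fs,
                        duration_s = 0.012)
  fp <- apply_lowpass(pulse, 10e3)
  expect_lt(abs(min(fp$current_pA) - 50), 0.01 * 50)

  expect_error(apply_lowpass(const, fs / 2), class = "porekin_bad_filter")
})

test_that("filtering then detection recovers nearly all events longer than 5 rise times", {
  p <- sim_params(100, 50, rate_on_true = 20, rate_off_true = 1500,
                  noise_sd_pA = 0, filter_cutoff_Hz = 10e3,
                  sampling_rate_Hz = 80e3, duration_s = 30, seed = 3)
  tr <- simulate_trace(p)
  ev <- detect_events(tr, levels = c(open = 100, blocked = 50))
  truth <- trace_truth(tr)
  truth <- truth[truth$state == "blocked", ]
  long <- truth[truth$end_s - truth$start_s >= 5 * 34e-6, ]
  hit <- vapply(long$start_s, function(s) {
    any(abs(ev$start_s - s) < 50e-6)
  }, logical(1))
  expect_gte(mean(hit), 0.99)
})

test_that("trace CSV round trip preserves samples and supports the detection path", {
  p <- sim_params(100, 50, 30, 800, duration_s = 1, sampling_rate_Hz = 2e4,
                  filter_cutoff_Hz = 5e3, noise_sd_pA = 1, seed = 5)
  tr <- simulate_trace(p)
  path <- withr::local_tempfile(fileext = ".csv")
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path, truth_path = tpath)
  back <- read_trace_csv(path)
  expect_equal(back$current_pA, tr$current_pA, tolerance = 1e-9)
  expect_equal(trace_dt(back), trace_dt(tr), tolerance = 1e-9)
  truth_back <- readr::read_csv(tpath, show_col_types = FALSE)
  expect_equal(nrow(truth_back), nrow(trace_truth(tr)))
})
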