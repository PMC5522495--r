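# shared fixtures: all built in code at test time

ref <- porekin::reference_conditions()

# a square-wave trace with prescribed event starts/durations (noiseless,
# unfiltered unless filtered afterwards)
square_trace <- function(event_starts_s, event_durations_s,
                         open = 100, blocked = 50,
                         fs = 80e3, duration_s = NULL) {
  if (is.null(duration_s)) {
    duration_s <- max(event_starts_s + event_durations_s) + 0.01
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- rep(open, n)
  for (i in seq_along(event_starts_s)) {
    sel <- t >= event_starts_s[i] &
      t < event_starts_s[i] + event_durations_s[i]
    x[sel] <- blocked
  }
  porekin::pore_trace(x, fs)
}

# generator settings for a reference condition row at a given analyte
# concentration (1 nS per mol/L open-pore conductance)
ref_sim_params <- function(row, analyte_M, duration_s = 60, seed = 1,
                           noise_sd_pA = 1.5, sampling_rate_Hz = 80e3,
                           filter_cutoff_Hz = 10e3) {
  I_o <- row$salt_M * row$voltage_mV
  porekin::sim_params(
    open_current_pA = I_o,
    blocked_current_pA = I_o * (1 - row$blockade_ratio),
    rate_on_true = row$k_on * analyte_M,
    rate_off_true = row$k_off,
    noise_sd_pA = noise_sd_pA,
    sampling_rate_Hz = sampling_rate_Hz,
    filter_cutoff_Hz = filter_cutoff_Hz,
    duration_s = duration_s, seed = seed
  )
}
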