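#' Simulation parameters for a two-state trace
#'
#' Parameters of the two-level renewal-process generator: current levels,
#' true capture/escape rates, noise, sampling and filtering. The generator
#' emulates the acquisition chain of a patch-clamp nanopore recording
#' (Axopatch-style amplifier, 80 kHz digitization, 10 kHz low-pass).
#'
#' @param open_current_pA open-pore current level I_o, pA
#' @param blocked_current_pA blocked-pore current level, pA; must satisfy
#'   `0 <= |blocked| < |open|`
#' @param rate_on_true capture (association) rate, 1/s; the open-state
#'   lifetime is exponential with this rate
#' @param rate_off_true escape (dissociation) rate, 1/s; the blocked-state
#'   lifetime is exponential with this rate
#' @param noise_sd_pA additive Gaussian noise standard deviation, pA. The
#'   default 1.5 pA RMS is typical of the recording configuration emulated
#'   here; it is a fixture parameter, not a measured value.
#' @param sampling_rate_Hz sampling frequency, Hz (default 80 kHz)
#' @param filter_cutoff_Hz low-pass cutoff, Hz (default 10 kHz); `NA`
#'   disables filtering. Must be below Nyquist.
#' @param duration_s trace duration, s
#' @param seed integer RNG seed; identical `(params, seed)` give
#'   byte-identical traces
#' @return a list of class `sim_params`
#' @export
#' @examples
#' sim_params(100, 50, rate_on_true = 5, rate_off_true = 2000, duration_s = 1)
sim_params <- function(open_current_pA, blocked_current_pA,
                       rate_on_true, rate_off_true,
                       noise_sd_pA = 1.5,
                       sampling_rate_Hz = 80e3,
                       filter_cutoff_Hz = 10e3,
                       duration_s = 60,
                       seed = 1L) {
  for (nm in c("rate_on_true", "rate_off_true", "sampling_rate_Hz",
               "duration_s")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm),
            class = "porekin_bad_sim_params")
    }
  }
  if (abs(blocked_current_pA) >= abs(open_current_pA)) {
    abort("`blocked_current_pA` must be smaller in magnitude than `open_current_pA`.",
          class = "porekin_bad_sim_params")
  }
  if (noise_sd_pA < 0) {
    abort("`noise_sd_pA` must be non-negative.", class = "porekin_bad_sim_params")
  }
  if (!is.na(filter_cutoff_Hz) && sampling_rate_Hz < 2 * filter_cutoff_Hz) {
    abort("`sampling_rate_Hz` must be at least twice `filter_cutoff_Hz`.",
          class = "porekin_bad_sim_params")
  }
  structure(
    list(
      open_current_pA = open_current_pA,
      blocked_current_pA = blocked_current_pA,
      rate_on_true = rate_on_true,
      rate_off_true = rate_off_true,
      noise_sd_pA = noise_sd_pA,
      sampling_rate_Hz = sampling_rate_Hz,
      filter_cutoff_Hz = filter_cutoff_Hz,
      duration_s = duration_s,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Construct a trace from a current sample vector
#'
#' Wraps a uniformly sampled current record as a `pore_trace`, the
#' container consumed by the detection and filtering functions. Useful for
#' user data already in memory; CSV ingestion is via [read_trace_csv()].
#'
#' @param current_pA numeric vector of current samples, pA
#' @param sampling_rate_Hz sampling frequency, Hz
#' @param cond optional [condition()] metadata
#' @return a `pore_trace` tibble
#' @export
pore_trace <- function(current_pA, sampling_rate_Hz, cond = NULL) {
  assert_positive_scalar(sampling_rate_Hz, "sampling_rate_Hz")
  new_pore_trace(current_pA, 1 / sampling_rate_Hz, condition = cond)
}

new_pore_trace <- function(current_pA, dt, condition = NULL, truth = NULL,
                           filter_cutoff_Hz = NA_real_) {
  n <- length(current_pA)
  out <- tibble(time_s = (seq_len(n) - 1) * dt, current_pA = current_pA)
  attr(out, "dt") <- dt
  attr(out, "sampling_rate_Hz") <- 1 / dt
  attr(out, "condition") <- condition
  attr(out, "truth") <- truth
  attr(out, "filter_cutoff_Hz") <- filter_cutoff_Hz
  class(out) <- c("pore_trace", class(out))
  out
}

#' Simulate a two-state nanopore current trace
#'
#' Generates an alternating open/blocked state sequence in continuous time
#' (i.i.d. exponential open lifetimes with rate `rate_on_true` and blocked
#' lifetimes with rate `rate_off_true`), samples it onto a uniform grid,
#' adds per-sample Gaussian noise, and optionally applies the Gaussian
#' low-pass filter. Ground-truth state intervals (unfiltered, continuous
#' time) are stored on the trace so downstream detection and estimation can
#' be validated by parameter recovery. State intervals shorter than one
#' sample are retained in the truth but may be invisible in the sampled
#' record — deliberate, so that censoring is exercised.
#'
#' @param params a [sim_params()] object
#' @param cond optional [condition()] to attach as metadata
#' @return a `pore_trace` tibble with columns `time_s`, `current_pA`;
#'   attributes carry `dt`, the condition and the truth interval table
#'   (`state`, `start_s`, `end_s` tiling `[0, duration]`)
#' @export
#' @examples
#' tr <- simulate_trace(sim_params(100, 50, 10, 10, noise_sd_pA = 0,
#'                                 filter_cutoff_Hz = NA, duration_s = 1,
#'                                 sampling_rate_Hz = 1e4, seed = 7))
#' trace_truth(tr)
simulate_trace <- function(params, cond = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    # draw alternating exponential lifetimes until the trace is covered
    durs <- numeric(0)
    total <- 0
    n_chunk <- max(
      64L,
      ceiling(2 * p$duration_s / (1 / p$rate_on_true + 1 / p$rate_off_true))
    )
    while (total < p$duration_s) {
      open_d <- rexp(n_chunk, rate = p$rate_on_true)
      blocked_d <- rexp(n_chunk, rate = p$rate_off_true)
      chunk <- as.vector(rbind(open_d, blocked_d))
      durs <- c(durs, chunk)
      total <- total + sum(chunk)
    }
    ends <- cumsum(durs)
    keep <- seq_len(which(ends >= p$duration_s)[1])
    durs <- durs[keep]
    ends <- ends[keep]
    starts <- c(0, ends[-length(ends)])
    state <- rep(c("open", "blocked"), length.out = length(durs))
    ends[length(ends)] <- p$duration_s

    dt <- 1 / p$sampling_rate_Hz
    n <- round(p$duration_s / dt)
    tgrid <- (seq_len(n) - 1) * dt
    idx <- findInterval(tgrid, starts)
    level <- ifelse(state[idx] == "open", p$open_current_pA,
                    p$blocked_current_pA)
    if (p$noise_sd_pA > 0) level <- level + rnorm(n, sd = p$noise_sd_pA)

    truth <- tibble(state = state, start_s = starts, end_s = ends)
    tr <- new_pore_trace(level, dt, condition = cond, truth = truth)
    if (!is.na(p$filter_cutoff_Hz)) {
      tr <- apply_lowpass(tr, p$filter_cutoff_Hz)
    }
    tr
  })
}

#' Ground-truth state intervals of a simulated trace
#'
#' @param trace a `pore_trace`
#' @return tibble with `state`, `start_s`, `end_s`, or `NULL` for traces
#'   without annotations (e.g. read from user CSV)
#' @export
trace_truth <- function(trace) attr(trace, "truth")

#' Trace sampling interval
#' @param trace a `pore_trace`
#' @return dt in seconds
#' @export
trace_dt <- function(trace) attr(trace, "dt")

#' Condition metadata attached to a trace or event table
#' @param x a `pore_trace` or `pore_events` object
#' @return a `pore_condition` tibble or `NULL`
#' @export
trace_condition <- function(x) attr(x, "condition")

#' Apply a Gaussian low-pass filter to a trace
#'
#' Zero-phase Gaussian FIR smoothing, the standard software filter for
#' single-channel records: DC gain exactly 1, 10–90% rise time
#' `0.3396/cutoff` (≈34 µs at 10 kHz), no overshoot. Plateau amplitudes of
#' events much longer than the rise time are preserved. Edges are handled by
#' replicate-padding so the output has the same length as the input.
#'
#' @param trace a `pore_trace`
#' @param cutoff_Hz -3 dB cutoff frequency; must be below Nyquist
#' @return a filtered `pore_trace` (truth annotations carried over)
#' @export
apply_lowpass <- function(trace, cutoff_Hz) {
  assert_positive_scalar(cutoff_Hz, "cutoff_Hz")
  fs <- attr(trace, "sampling_rate_Hz")
  if (cutoff_Hz >= fs / 2) {
    abort("`cutoff_Hz` must be below the Nyquist frequency.",
          class = "porekin_bad_filter")
  }
  sigma_samples <- 0.1325 / cutoff_Hz * fs
  radius <- max(1L, ceiling(4 * sigma_samples))
  kern <- dnorm(seq(-radius, radius), sd = sigma_samples)
  kern <- kern / sum(kern)
  x <- trace$current_pA
  xp <- c(rep(x[1], radius), x, rep(x[length(x)], radius))
  y <- stats::filter(xp, kern, sides = 2)
  y <- as.numeric(y[(radius + 1):(radius + length(x))])
  out <- new_pore_trace(y, trace_dt(trace),
                        condition = trace_condition(trace),
                        truth = trace_truth(trace),
                        filter_cutoff_Hz = cutoff_Hz)
  out
}

#' Write / read a trace as CSV
#'
#' Two-column CSV (`time_s`, `current_pA`, with header). Ground truth, when
#' present, is written next to it as a three-column interval table
#' (`state`, `start_s`, `end_s`).
#'
#' @param trace a `pore_trace`
#' @param path output CSV path
#' @param truth_path optional path for the truth interval table
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(trace, path, truth_path = NULL) {
  readr::write_csv(tibble(time_s = trace$time_s,
                          current_pA = trace$current_pA), path)
  if (!is.null(truth_path) && !is.null(trace_truth(trace))) {
    readr::write_csv(trace_truth(trace), truth_path)
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @param cond optional [condition()] to attach on read
#' @export
read_trace_csv <- function(path, cond = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), current_pA = readr::col_double()
  ))
  if (nrow(df) < 2) abort("Trace CSV must contain at least two samples.",
                          class = "porekin_bad_trace")
  dt <- stats::median(diff(df$time_s))
  new_pore_trace(df$current_pA, dt, condition = cond)
}

#' @export
autoplot.pore_trace <- function(object, max_points = 2e5, ...) {
  df <- object
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  ggplot(df, aes(x = .data$time_s, y = .data$current_pA)) +
    geom_line(linewidth = 0.2) +
    labs(x = "time (s)", y = "current (pA)") +
    theme_minimal()
}
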