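#' All-points current histogram
#'
#' Histogram of every sample in the trace on a regular pA grid — the
#' standard "all-events" amplitude display for two-level single-channel
#' records, and the input to [detect_levels()].
#'
#' @param trace a `pore_trace`
#' @param bin_width_pA bin width in pA (default 0.25)
#' @return tibble of class `pore_histogram` with `current_pA` (bin centers)
#'   and `count`; counts sum to the number of samples
#' @export
all_points_histogram <- function(trace, bin_width_pA = 0.25) {
  assert_positive_scalar(bin_width_pA, "bin_width_pA")
  x <- trace$current_pA
  if (length(x) == 0) abort("Trace is empty.", class = "porekin_bad_trace")
  lo <- floor(min(x) / bin_width_pA) * bin_width_pA - bin_width_pA / 2
  centers <- seq(lo + bin_width_pA / 2,
                 max(x) + bin_width_pA, by = bin_width_pA)
  idx <- pmin(length(centers),
              pmax(1L, floor((x - lo) / bin_width_pA) + 1L))
  counts <- tabulate(idx, nbins = length(centers))
  out <- tibble(current_pA = centers, count = counts)
  attr(out, "bin_width_pA") <- bin_width_pA
  attr(out, "n_samples") <- length(x)
  class(out) <- c("pore_histogram", class(out))
  out
}

#' Detect open and blocked current levels from an all-points histogram
#'
#' Finds the modes of the amplitude histogram, keeps those separated by at
#' least `min_separation_pA`, and assigns the larger-magnitude level to the
#' open pore. Each level is then refined as the count-weighted mean of the
#' bins within `refine_window_pA` of its mode, which centers the estimate on
#' the underlying noisy level rather than on a single bin.
#'
#' @param hist a `pore_histogram`
#' @param min_separation_pA minimum mode separation (default 5 pA)
#' @param min_count_frac a mode must hold at least this fraction of the
#'   total samples (default 2e-5) to count as a level; low enough that the
#'   blocked level of a sparsely occupied pore still registers, high enough
#'   to reject bins populated only by level-transition samples
#' @param top_two if `TRUE` (default) and more than two modes qualify, the
#'   two most populated are returned; if `FALSE`, more than two modes is an
#'   error
#' @param refine_window_pA half-width of the refinement window (default 4 pA)
#' @return named numeric vector `c(open = I_o, blocked = I_blocked)` in pA
#' @export
detect_levels <- function(hist, min_separation_pA = 5,
                          min_count_frac = 2e-5, top_two = TRUE,
                          refine_window_pA = 4) {
  stopifnot(inherits(hist, "pore_histogram"))
  counts <- hist$count
  centers <- hist$current_pA
  n_tot <- sum(counts)
  bw <- attr(hist, "bin_width_pA")
  half <- max(1L, round(min_separation_pA / bw / 2))
  # local maxima over a +/- half-window, above the occupancy floor
  is_peak <- vapply(seq_along(counts), function(i) {
    lo <- max(1L, i - half); hi <- min(length(counts), i + half)
    counts[i] == max(counts[lo:hi]) && counts[i] >= max(5, min_count_frac * n_tot)
  }, logical(1))
  peak_idx <- which(is_peak)
  if (length(peak_idx) == 0) {
    abort("No populated current levels found in histogram.",
          class = "porekin_no_blockades")
  }
  # greedy selection by prominence with separation constraint
  ord <- peak_idx[order(counts[peak_idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(centers[i] - centers[kept]) >= min_separation_pA)) {
      kept <- c(kept, i)
    }
  }
  if (length(kept) < 2) {
    abort("Histogram is unimodal: no blockades detected.",
          class = "porekin_no_blockades")
  }
  if (length(kept) > 2 && !top_two) {
    abort(sprintf("Found %d current levels; expected two (set `top_two = TRUE` to keep the most populated pair).",
                  length(kept)),
          class = "porekin_multimodal")
  }
  kept <- kept[1:2]
  refine <- function(i) {
    sel <- abs(centers - centers[i]) <= refine_window_pA
    weighted.mean(centers[sel], counts[sel])
  }
  levels <- vapply(kept, refine, numeric(1))
  open <- levels[which.max(abs(levels))]
  blocked <- levels[which.min(abs(levels))]
  c(open = open, blocked = blocked)
}

#' Idealize a trace into a blockade event table
#'
#' Hysteresis thresholding between the two detected levels: an event starts
#' when the current crosses 75% of the open-to-blocked gap (i.e. comes
#' within 25% of the blocked level) and ends when it recovers past 25% of
#' the gap. Because entry and exit both trigger at 75% of their respective
#' transitions, dwell durations of events longer than the filter rise time
#' are unbiased. Events shorter than `min_duration_s` are discarded and the
#' cutoff is recorded as the censoring floor consumed by the downstream
#' censored maximum-likelihood rate estimator.
#'
#' @param trace a `pore_trace`
#' @param levels named vector `c(open=, blocked=)` from [detect_levels()];
#'   if `NULL`, levels are detected from the all-points histogram
#' @param min_duration_s minimum resolvable event duration; defaults to
#'   twice the filter rise time (≈68 µs at 10 kHz), or `2 * dt` for
#'   unfiltered traces. Must be at least `2 * dt`.
#' @param amplitude_trim_s plateau trim on each side when computing the
#'   in-event mean amplitude; defaults to the filter rise time
#' @return a tibble of class `pore_events` with columns `start_s`, `end_s`,
#'   `dwell_s`, `tau_on_s` (gap preceding each event; `NA` for the first,
#'   renewal-process convention), `dI_pA` (signed mean in-event current
#'   minus I_o). Attributes: `open_level_pA`, `blocked_level_pA`,
#'   `censor_floor_s`, `condition`.
#' @export
detect_events <- function(trace, levels = NULL, min_duration_s = NULL,
                          amplitude_trim_s = NULL) {
  if (is.null(levels)) levels <- detect_levels(all_points_histogram(trace))
  open <- unname(levels["open"]); blocked <- unname(levels["blocked"])
  if (!is.finite(open) || !is.finite(blocked)) {
    abort("`levels` must contain finite `open` and `blocked` entries.",
          class = "porekin_bad_argument")
  }
  dt <- trace_dt(trace)
  gap <- open - blocked
  x <- trace$current_pA

  # noise estimate: sd within the open-side band (truncation-biased when the
  # noise rivals the gap) guarded by a difference-based robust estimate that
  # is insensitive to the two-level structure
  open_band <- abs(x - open) <= abs(gap) * 0.25
  sd_band <- if (sum(open_band) > 10) sd(x[open_band]) else 0
  sd_diff <- stats::mad(diff(x)) / sqrt(2)
  noise_sd <- max(sd_band, sd_diff)
  if (abs(gap) < 4 * noise_sd) {
    abort("Open and blocked levels are closer than 4x the noise sd: insufficient separation.",
          class = "porekin_insufficient_separation")
  }

  cutoff <- attr(trace, "filter_cutoff_Hz")
  rise <- if (!is.null(cutoff) && is.finite(cutoff)) gaussian_rise_time(cutoff) else 0
  if (is.null(min_duration_s)) min_duration_s <- max(2 * rise, 2 * dt)
  if (min_duration_s < 2 * dt) {
    abort("`min_duration_s` must be at least two sampling intervals.",
          class = "porekin_bad_argument")
  }
  if (is.null(amplitude_trim_s)) amplitude_trim_s <- rise

  enter_thr <- open - 0.75 * gap   # within 25% of blocked level
  exit_thr <- open - 0.25 * gap    # recovered past 75% toward open
  below <- if (gap > 0) x < enter_thr else x > enter_thr
  above <- if (gap > 0) x > exit_thr else x < exit_thr
  s <- rep(NA_real_, length(x))
  s[below] <- 1; s[above] <- 0
  s <- fill_forward(s, init = 0)

  r <- rle(s)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  blocked_runs <- which(r$values == 1)
  n_all <- length(blocked_runs)
  if (n_all == 0) {
    ev <- tibble(start_s = numeric(0), end_s = numeric(0),
                 dwell_s = numeric(0), tau_on_s = numeric(0),
                 dI_pA = numeric(0))
  } else {
    st <- starts_idx[blocked_runs]; en <- ends_idx[blocked_runs]
    start_s <- (st - 1) * dt
    end_s <- en * dt
    dwell_s <- end_s - start_s
    trim_n <- ceiling(amplitude_trim_s / dt)
    amp <- vapply(seq_along(st), function(i) {
      a <- st[i] + trim_n; b <- en[i] - trim_n
      if (b - a >= 0) mean(x[a:b]) else x[st[i]:en[i]][which.max(abs(x[st[i]:en[i]] - open))]
    }, numeric(1))
    ev <- tibble(start_s = start_s, end_s = end_s, dwell_s = dwell_s,
                 dI_pA = amp - open)
    keep <- ev$dwell_s >= min_duration_s
    ev <- ev[keep, ]
    ev$tau_on_s <- c(NA_real_, ev$start_s[-1] - ev$end_s[-nrow(ev)])[seq_len(nrow(ev))]
    ev <- ev[, c("start_s", "end_s", "dwell_s", "tau_on_s", "dI_pA")]
  }
  attr(ev, "open_level_pA") <- open
  attr(ev, "blocked_level_pA") <- blocked
  attr(ev, "censor_floor_s") <- min_duration_s
  attr(ev, "noise_sd_pA") <- noise_sd
  attr(ev, "condition") <- trace_condition(trace)
  class(ev) <- c("pore_events", class(ev))
  ev
}

#' Event-table level accessors
#' @param events a `pore_events` table
#' @return scalar level (pA) or censoring floor (s)
#' @export
open_level <- function(events) attr(events, "open_level_pA")

#' @rdname open_level
#' @export
blocked_level <- function(events) attr(events, "blocked_level_pA")

#' @rdname open_level
#' @export
censor_floor <- function(events) attr(events, "censor_floor_s")

#' Mean relative current blockade
#'
#' Average over events of `|dI_block| / |I_o|` with its standard error —
#' the fractional current obstruction used as a proxy for the electrolyte
#' volume excluded by the analyte. Invariant under rescaling the current
#' units of the trace.
#'
#' @param events a non-empty `pore_events` table
#' @return one-row tibble: `ratio`, `se`, `n_events`
#' @export
relative_blockade <- function(events) {
  stopifnot(inherits(events, "pore_events"))
  if (nrow(events) == 0) {
    abort("Event table is empty: relative blockade is undefined.",
          class = "porekin_empty_events")
  }
  r <- abs(events$dI_pA) / abs(open_level(events))
  tibble(ratio = mean(r), se = sd(r) / sqrt(length(r)), n_events = length(r))
}

#' Write an event table as CSV with a JSON sidecar
#'
#' The CSV holds one row per event (`start_s`, `end_s`, `dwell_s`,
#' `tau_on_s`, `dI_pA`); the sidecar records the detected levels, the
#' censoring floor and any condition metadata.
#'
#' @param events a `pore_events` table
#' @param path CSV output path; the sidecar is written at `<path>.json`
#' @return `path`, invisibly
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(as_tibble(events), path)
  meta <- list(
    open_level_pA = open_level(events),
    blocked_level_pA = blocked_level(events),
    censor_floor_s = censor_floor(events),
    condition = if (!is.null(trace_condition(events)))
      as.list(trace_condition(events)) else NULL
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
autoplot.pore_histogram <- function(object, ...) {
  ggplot(object, aes(x = .data$current_pA, y = .data$count)) +
    geom_step() +
    labs(x = "current (pA)", y = "samples") +
    theme_minimal()
}

#' Dwell-time histogram plot for an event table
#'
#' @param events a `pore_events` table
#' @param which `"dwell"` (blockade durations) or `"tau_on"` (inter-event)
#' @param bins histogram bin count
#' @return a ggplot
#' @export
plot_dwell_histogram <- function(events, which = c("dwell", "tau_on"),
                                 bins = 30) {
  which <- match.arg(which)
  v <- if (which == "dwell") events$dwell_s else events$tau_on_s
  df <- tibble(t = v[is.finite(v)])
  ggplot(df, aes(x = .data$t)) +
    geom_histogram(bins = bins, fill = "grey60", colour = "grey30") +
    labs(x = sprintf("%s (s)", if (which == "dwell") "dwell time" else
      "inter-event time"), y = "events") +
    theme_minimal()
}
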