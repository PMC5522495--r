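# internal helpers

# forward-fill NA entries of a numeric vector; positions before the first
# non-NA get `init`
fill_forward <- function(x, init) {
  idx <- which(!is.na(x))
  if (length(idx) == 0L) return(rep(init, length(x)))
  vals <- c(init, x[idx])
  vals[findInterval(seq_along(x), idx) + 1L]
}

# check a scalar is a single positive finite number
assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "porekin_bad_argument")
  }
  invisible(x)
}

# 10-90% rise time of the package's Gaussian low-pass filter, seconds
gaussian_rise_time <- function(cutoff_Hz) 0.3396 / cutoff_Hz

# vcov() without the benign "essentially perfect fit" warning that
# summary.lm raises on zero-residual (noiseless oracle) data
quiet_vcov <- function(fit) {
  withCallingHandlers(
    vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}
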