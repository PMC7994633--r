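# Shared fixtures and independent oracles for the test suite.

fs_test <- 4000

# Analytic noiseless template: sum of Gaussian bumps evaluated directly on
# the epoch time axis (ms). Independent of the generator's add_bump path.
analytic_template <- function(components, fs = fs_test) {
  t_ms <- seq(-1, 2 - 1 / fs, by = 1 / fs) * 1000
  out <- numeric(length(t_ms))
  for (c_ in components)
    out <- out + c_$amplitude_uv *
      exp(-(t_ms - c_$latency_ms)^2 / (2 * c_$width_sd_ms^2))
  out
}

# Brute-force extremum scan over a latency window (ms) of a trace on the
# epoch axis: loops over every sample, no vectorised shortcuts.
brute_extremum <- function(trace, lo_ms, hi_ms, fs = fs_test,
                           find = c("min", "max")) {
  find <- match.arg(find)
  t_ms <- seq(-1, 2 - 1 / fs, by = 1 / fs) * 1000
  best_i <- NA_integer_
  for (i in seq_along(trace)) {
    if (t_ms[i] < lo_ms || t_ms[i] >= hi_ms) next
    if (is.na(best_i) ||
        (find == "min" && trace[i] < trace[best_i]) ||
        (find == "max" && trace[i] > trace[best_i])) best_i <- i
  }
  list(latency_ms = t_ms[best_i], amplitude_uv = trace[best_i])
}

# ANOVA mean-squares oracle for ICC(A,k), computed through stats::aov
# rather than the package's direct sums.
icc_aov_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  d <- data.frame(y = as.vector(mat),
                  row = factor(rep(seq_len(n), times = k)),
                  col = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ row + col, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (msc - mse) / n)
}

# A well-separated, narrow-component ground truth where component overlap
# is numerically negligible (cross-talk < 1e-12 of the amplitudes).
separated_truth <- function(noise_rms = 0, jitter = 0) {
  ep_ground_truth(
    n1 = list(latency_ms = 150, amplitude_uv = -8, width_sd_ms = 8),
    n2 = list(latency_ms = 300, amplitude_uv = -12, width_sd_ms = 10),
    p2 = list(latency_ms = 500, amplitude_uv = 14, width_sd_ms = 10),
    latency_jitter_sd_ms = jitter, noise_rms_uv = noise_rms)
}

# Build an epoch-axis trace (length 3*fs) from a function of time in ms.
trace_from <- function(f, fs = fs_test) {
  t_ms <- seq(-1, 2 - 1 / fs, by = 1 / fs) * 1000
  vapply(t_ms, f, numeric(1))
}
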