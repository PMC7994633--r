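#' 1/f^beta background noise
#'
#' Spectrally shaped Gaussian noise generated by scaling the discrete
#' Fourier transform of white noise by `f^(-beta/2)` (DC removed) and
#' inverting, then rescaling to the requested RMS. The periodogram slope of
#' the result is -beta over the analysis band.
#'
#' @param n number of samples.
#' @param beta spectral exponent (1 = pink noise).
#' @param fs sample rate, Hz (only sets the physical frequency axis).
#' @param rms target root-mean-square amplitude.
#' @param seed optional seed.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, beta = 1, fs = 4000, rms = 1, seed = NULL) {
  stopifnot(n >= 2, rms >= 0)
  maybe_seed(seed)
  if (rms == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  # synthesize the spectrum directly: independent Gaussian real/imaginary
  # parts at each positive frequency, Hermitian-symmetrized, DC removed
  npair <- (m - 1) %/% 2                 # conjugate-paired positive bins
  has_nyquist <- m %% 2 == 0
  nbin <- npair + has_nyquist
  re <- stats::rnorm(nbin)
  im <- stats::rnorm(nbin)
  f <- (1:nbin) * fs / m
  gain <- f^(-beta / 2)
  pos <- complex(real = re, imaginary = im) * gain
  if (has_nyquist)                       # Nyquist bin must be real
    pos[nbin] <- complex(real = re[nbin], imaginary = 0) * gain[nbin]
  spec <- c(0, pos, Conj(pos[npair:1]))  # DC removed, Hermitian symmetry
  stopifnot(length(spec) == m)
  x <- Re(stats::fft(spec, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x * rms / rms(x)
}

# Sample axis of one epoch: [-1 s, 2 s), t = 0 at index fs + 1.
epoch_time <- function(fs = 4000) seq(-1, 2 - 1 / fs, by = 1 / fs)

default_channels <- function() c("Cz", "C3", "C4", "Fz", "A1", "A2")

# One jittered latency, resampled (bounded retry) so the component peak
# stays inside the post-stimulus interval [0, 2) s.
jitter_latency <- function(latency_ms, jitter_sd_ms, max_tries = 100) {
  if (jitter_sd_ms == 0) return(latency_ms)
  for (i in seq_len(max_tries)) {
    l <- latency_ms + stats::rnorm(1, 0, jitter_sd_ms)
    if (l > 0 && l < 2000) {
      if (i > 1) warning("latency jitter resampled to stay within the epoch")
      return(l)
    }
  }
  warning("latency jitter exhausted retries; using the nominal latency")
  latency_ms
}

# Add one Gaussian component bump (amplitude uV, latency/width ms) to a
# channel trace sampled at fs, with t = 0 at sample `t0` (1-based).
add_bump <- function(trace, fs, t0, latency_ms, amplitude_uv, width_sd_ms) {
  n <- length(trace)
  centre <- t0 + latency_ms / 1000 * fs
  half <- ceiling(6 * width_sd_ms / 1000 * fs)
  idx <- max(1, floor(centre - half)):min(n, ceiling(centre + half))
  t_ms <- (idx - t0) / fs * 1000
  trace[idx] <- trace[idx] +
    amplitude_uv * exp(-(t_ms - latency_ms)^2 / (2 * width_sd_ms^2))
  trace
}

#' Synthesize a single trigger-locked epoch
#'
#' Produces one epoch of `3 * fs` samples spanning \[-1 s, 2 s) (half-open;
#' t = 0 at index `fs + 1`). Each component is a Gaussian bump at its
#' (jittered) latency on its mapped channel; every channel receives
#' independent 1/f^beta background noise scaled to the ground-truth RMS.
#'
#' @param truth an [ep_ground_truth()].
#' @param seed optional seed.
#' @param fs sample rate, Hz.
#' @param channels channel labels (must include the mapped channels).
#' @return matrix channels x time (microvolts) with channel rownames.
#' @export
synthesize_epoch <- function(truth, seed = NULL, fs = 4000,
                             channels = default_channels()) {
  stopifnot(inherits(truth, "noxep_truth"))
  maybe_seed(seed)
  n <- 3 * fs
  t0 <- fs + 1
  dat <- matrix(0, nrow = length(channels), ncol = n,
                dimnames = list(channels, NULL))
  for (ch in channels)
    dat[ch, ] <- pink_noise(n, beta = truth$noise_exponent, fs = fs,
                            rms = truth$noise_rms_uv)
  for (nm in names(truth$components)) {
    comp <- truth$components[[nm]]
    ch <- truth$channel_map[[nm]]
    if (!ch %in% channels) stop(sprintf("channel %s missing for %s", ch, nm))
    l <- jitter_latency(comp$latency_ms, truth$latency_jitter_sd_ms)
    dat[ch, ] <- add_bump(dat[ch, ], fs, t0, l, comp$amplitude_uv,
                          comp$width_sd_ms)
  }
  dat
}

#' Synthesize a full stimulation session
#'
#' In continuous mode, builds a multi-channel recording with
#' `train$n_stimuli` triggers separated by inter-stimulus intervals drawn
#' uniformly from `train$isi_range`, 2 s of lead-in and 3 s of tail, and the
#' ground-truth components added at each trigger (independent latency jitter
#' per trigger). In epoched mode, returns an [epoch_set()] of
#' `train$n_stimuli` independent raw (not yet baseline-corrected) epochs.
#'
#' @param truth an [ep_ground_truth()].
#' @param train a [stimulus_train()].
#' @param continuous logical; continuous recording or epoch set.
#' @param seed integer seed (identical seeds give bit-identical output).
#' @param fs sample rate, Hz (4000 by default).
#' @param channels channel labels.
#' @return a `noxep_recording` (continuous) or `noxep_epochs` (epoched).
#' @export
synthesize_session <- function(truth, train, continuous = TRUE, seed = NULL,
                               fs = 4000, channels = default_channels()) {
  stopifnot(inherits(truth, "noxep_truth"), inherits(train, "noxep_train"))
  maybe_seed(seed %||% train$seed)
  n_stim <- train$n_stimuli
  if (!continuous) {
    dat <- array(0, dim = c(n_stim, length(channels), 3 * fs),
                 dimnames = list(NULL, channels, NULL))
    for (i in seq_len(n_stim))
      dat[i, , ] <- synthesize_epoch(truth, seed = NULL, fs = fs,
                                     channels = channels)
    return(epoch_set(dat, fs = fs, baseline_corrected = FALSE,
                     ground_truth = truth))
  }
  gaps <- if (n_stim > 1) stats::runif(n_stim - 1, train$isi_range[1],
                                       train$isi_range[2]) else numeric(0)
  trig_t <- 2 + cumsum(c(0, gaps))          # >= 2 s lead-in
  total_s <- trig_t[n_stim] + 3             # >= 3 s tail
  n <- ceiling(total_s * fs)
  trig_samples <- as.integer(round(trig_t * fs)) + 1L
  traces <- lapply(channels, function(ch)
    pink_noise(n, beta = truth$noise_exponent, fs = fs,
               rms = truth$noise_rms_uv))
  names(traces) <- channels
  # jittered latencies drawn trigger-by-trigger, component within trigger
  for (s in trig_samples) {
    for (nm in names(truth$components)) {
      comp <- truth$components[[nm]]
      l <- jitter_latency(comp$latency_ms, truth$latency_jitter_sd_ms)
      ch <- truth$channel_map[[nm]]
      traces[[ch]] <- add_bump(traces[[ch]], fs, s, l, comp$amplitude_uv,
                               comp$width_sd_ms)
    }
  }
  dat <- do.call(rbind, traces)
  dimnames(dat) <- list(channels, NULL)
  structure(
    list(data = dat, sample_rate = fs, channel_labels = channels,
         trigger_samples = trig_samples, ground_truth = truth, seed = seed,
         provenance = list()),
    class = "noxep_recording")
}

#' @export
print.noxep_recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %d Hz, %d triggers\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              length(x$trigger_samples)))
  invisible(x)
}
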