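#' Epoch container
#'
#' Trials x channels x time array of trigger-locked EEG, sampled at `fs` Hz
#' over the half-open interval \[-1 s, 2 s) (t = 0 at index `fs + 1`).
#' Carries the rejection list, the generating ground truth when available,
#' and processing provenance (filter settings, seeds).
#'
#' @param data numeric array `epochs x channels x time` with channel
#'   dimnames.
#' @param fs sample rate, Hz.
#' @param baseline_corrected has the pre-stimulus mean been subtracted?
#' @param rejected integer indices of rejected epochs.
#' @param ground_truth optional [ep_ground_truth()].
#' @param provenance named list of processing decisions.
#' @return object of class `noxep_epochs`.
#' @export
epoch_set <- function(data, fs = 4000, baseline_corrected = FALSE,
                      rejected = integer(0), ground_truth = NULL,
                      provenance = list()) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 3 * fs,
            !is.null(dimnames(data)[[2]]))
  structure(
    list(data = data, sample_rate = fs,
         channel_labels = dimnames(data)[[2]],
         baseline_corrected = baseline_corrected,
         rejected = as.integer(rejected),
         ground_truth = ground_truth, provenance = provenance),
    class = "noxep_epochs")
}

#' @export
print.noxep_epochs <- function(x, ...) {
  cat(sprintf(
    "<epochs> %d epochs (%d rejected) x %d channels x %d samples @ %d Hz%s\n",
    dim(x$data)[1], length(x$rejected), dim(x$data)[2], dim(x$data)[3],
    x$sample_rate,
    if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

#' Design the offline bandpass filter
#'
#' Hamming-windowed FIR bandpass between `low` and `high` Hz. The filter
#' order follows the standard transition-band rule `3.3 * fs / delta_f`
#' with a 1 Hz transition at the low edge (the binding constraint for a
#' 1 Hz highpass), giving a linear-phase filter whose passband is flat to
#' better than 1% between 2 and 35 Hz with more than 20 dB attenuation at
#' 0.25 and 60 Hz.
#'
#' @param fs sample rate, Hz.
#' @param low,high band edges, Hz.
#' @param transition transition bandwidth at the low edge, Hz.
#' @return numeric vector of filter taps (odd length).
#' @export
design_bandpass <- function(fs = 4000, low = 1, high = 40, transition = 1) {
  stopifnot(fs > 2 * high, low > 0, high > low)
  n <- ceiling(3.3 * fs / transition)
  if (n %% 2 == 1) n <- n + 1            # even order -> odd, symmetric taps
  signal::fir1(n, c(low, high) / (fs / 2), type = "pass",
               window = signal::hamming(n + 1))
}

# Zero-phase FIR filtering: FFT convolution with group-delay compensation
# (taps are symmetric, delay = (length-1)/2). The filter spectrum is
# computed once and shared across channels.
fir_zerophase_multi <- function(x, taps) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x); nb <- length(taps)
  if (n < nb)
    stop("signal shorter than the filter; filter continuous data, not epochs")
  m <- stats::nextn(n + nb, c(2, 3, 5))
  tap_spec <- stats::fft(c(taps, numeric(m - nb)))
  delay <- (nb - 1) / 2
  pick <- (delay + 1):(delay + n)
  # work channel-by-channel on contiguous vectors, assemble once
  rows <- lapply(seq_len(nrow(x)), function(i) {
    conv <- Re(stats::fft(stats::fft(c(x[i, ], numeric(m - n))) * tap_spec,
                          inverse = TRUE)) / m
    conv[pick]
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- dimnames(x)
  if (vec) drop(out) else out
}

fir_zerophase <- function(x, taps) fir_zerophase_multi(x, taps)

#' Bandpass-filter a continuous recording
#'
#' Applies [design_bandpass()] to every channel with zero-phase (group-delay
#' compensated) application so component latencies are unbiased. Filtering
#' is done on the continuous record, before epoching, to keep filter
#' transients away from epoch edges.
#'
#' @param rec a `noxep_recording`.
#' @param low,high band edges, Hz.
#' @param transition low-edge transition bandwidth, Hz.
#' @return the filtered recording (provenance updated).
#' @export
bandpass <- function(rec, low = 1, high = 40, transition = 1) {
  stopifnot(inherits(rec, "noxep_recording"))
  taps <- design_bandpass(rec$sample_rate, low, high, transition)
  rec$data <- fir_zerophase_multi(rec$data, taps)
  rec$provenance$filter <- list(type = "FIR bandpass, Hamming window",
                                low_hz = low, high_hz = high,
                                transition_hz = transition,
                                n_taps = length(taps),
                                phase = "zero (group-delay compensated)")
  rec
}

#' Cut a continuous recording into baseline-corrected epochs
#'
#' One epoch per trigger, spanning one second pre-stimulus to two seconds
#' post-stimulus. Each epoch and channel has the mean over the full
#' pre-stimulus second \[-1, 0) subtracted. Triggers too close to the record
#' edges are skipped with a warning.
#'
#' @param rec a `noxep_recording`.
#' @param triggers trigger sample indices (defaults to the recording's).
#' @return a baseline-corrected [epoch_set()].
#' @export
epoch_recording <- function(rec, triggers = rec$trigger_samples) {
  stopifnot(inherits(rec, "noxep_recording"), length(triggers) >= 1)
  fs <- rec$sample_rate
  n <- ncol(rec$data)
  usable <- triggers - fs >= 1 & triggers + 2 * fs - 1 <= n
  if (any(!usable))
    warning(sprintf("%d trigger(s) too close to the record edge; skipped",
                    sum(!usable)))
  triggers <- triggers[usable]
  if (length(triggers) == 0) stop("no usable triggers")
  dat <- array(0, dim = c(length(triggers), nrow(rec$data), 3 * fs),
               dimnames = list(NULL, rownames(rec$data), NULL))
  for (i in seq_along(triggers))
    dat[i, , ] <- rec$data[, (triggers[i] - fs):(triggers[i] + 2 * fs - 1)]
  es <- epoch_set(dat, fs = fs, baseline_corrected = FALSE,
                  ground_truth = rec$ground_truth,
                  provenance = rec$provenance)
  baseline_correct(es)
}

#' Subtract the pre-stimulus baseline
#'
#' Per epoch and channel, subtracts the mean over the full pre-stimulus
#' second \[-1, 0).
#'
#' @param es an [epoch_set()].
#' @return the corrected epoch set.
#' @export
baseline_correct <- function(es) {
  stopifnot(inherits(es, "noxep_epochs"))
  if (es$baseline_corrected) return(es)
  fs <- es$sample_rate
  base <- apply(es$data[, , seq_len(fs), drop = FALSE], c(1, 2), mean)
  es$data <- es$data - array(base, dim = dim(es$data))  # broadcast over time
  es$baseline_corrected <- TRUE
  es
}

#' Amplitude-criterion artifact rejection
#'
#' Epochs whose peak-to-peak amplitude on any channel exceeds the criterion
#' (default 150 uV) are marked rejected; they stay in the container and are
#' excluded from averages, never deleted. A deterministic threshold rule
#' standing where interactive component-based artifact removal would sit in
#' a laboratory pipeline.
#'
#' @param es an [epoch_set()].
#' @param criterion_uv rejection threshold, microvolts peak-to-peak (> 0;
#'   `Inf` disables rejection).
#' @return the epoch set with its `rejected` list populated.
#' @export
reject_artifacts <- function(es, criterion_uv = 150) {
  stopifnot(inherits(es, "noxep_epochs"), criterion_uv > 0)
  ptp <- apply(es$data, c(1, 2), function(v) max(v) - min(v))
  bad <- which(apply(ptp, 1, max) > criterion_uv)
  if (length(bad) == dim(es$data)[1])
    stop("all epochs exceed the artifact criterion; session unusable")
  es$rejected <- as.integer(bad)
  es$provenance$rejection <- list(criterion_uv = criterion_uv,
                                  n_rejected = length(bad))
  es
}

#' Derive the analysis montages
#'
#' The vertex montage (N2/P2) is Cz referenced to linked ears,
#' `Cz - mean(A1, A2)`; the contralateral montage (N1) is the central
#' electrode opposite the stimulated arm referenced to Fz: `C4 - Fz` for
#' left-side stimulation, `C3 - Fz` for right.
#'
#' @param es an [epoch_set()].
#' @param stimulated_side `"left"` or `"right"`.
#' @return list with `vertex` and `contralateral` epoch x time matrices
#'   (all epochs, including rejected ones) plus the rejection list.
#' @export
derive_montages <- function(es, stimulated_side = c("left", "right")) {
  stimulated_side <- match.arg(stimulated_side)
  stopifnot(inherits(es, "noxep_epochs"))
  contra_ch <- if (stimulated_side == "left") "C4" else "C3"
  need <- c("Cz", "A1", "A2", contra_ch, "Fz")
  missing <- setdiff(need, es$channel_labels)
  if (length(missing) > 0)
    stop(sprintf("missing channel(s): %s", paste(missing, collapse = ", ")))
  vertex <- es$data[, "Cz", ] - (es$data[, "A1", ] + es$data[, "A2", ]) / 2
  contra <- es$data[, contra_ch, ] - es$data[, "Fz", ]
  if (dim(es$data)[1] == 1) {            # keep matrix shape for one epoch
    vertex <- matrix(vertex, nrow = 1)
    contra <- matrix(contra, nrow = 1)
  }
  list(vertex = vertex, contralateral = contra, rejected = es$rejected,
       sample_rate = es$sample_rate)
}

#' Average epochs, excluding rejected trials
#'
#' @param trace_matrix epochs x time matrix (e.g. a montage from
#'   [derive_montages()]).
#' @param rejected indices to exclude.
#' @return numeric vector, the averaged trace.
#' @export
average_epochs <- function(trace_matrix, rejected = integer(0)) {
  keep <- setdiff(seq_len(nrow(trace_matrix)), rejected)
  if (length(keep) == 0) stop("no non-rejected epochs to average")
  colMeans(trace_matrix[keep, , drop = FALSE])
}
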