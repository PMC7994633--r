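#' Analysis windows per modality
#'
#' The session SNR region of interest is 150-550 ms post-trigger for laser
#' and 300-650 ms for contact heat. Component search windows are centred on
#' the canonical component latencies per modality (laser N2 150-300 ms, P2
#' 250-450 ms; contact heat N2 300-500 ms, P2 400-650 ms) and are
#' configurable. Component presence is judged against the RMS of the 500 ms
#' immediately pre-trigger; the session gate uses the full pre-stimulus
#' second.
#'
#' @param modality `"chep"` or `"lep"`.
#' @param snr_roi,search_n2,search_p2 optional overrides, ms intervals.
#' @param pre_presence_ms length of the pre-trigger interval used for the
#'   component presence rule, ms.
#' @return object of class `noxep_roi`.
#' @export
roi_windows <- function(modality = c("chep", "lep"),
                        snr_roi = NULL, search_n2 = NULL, search_p2 = NULL,
                        pre_presence_ms = 500) {
  modality <- match.arg(modality)
  def <- if (modality == "lep") {
    list(snr_roi = c(150, 550), search_n2 = c(150, 300),
         search_p2 = c(250, 450))
  } else {
    list(snr_roi = c(300, 650), search_n2 = c(300, 500),
         search_p2 = c(400, 650))
  }
  out <- list(modality = modality,
              snr_roi = snr_roi %||% def$snr_roi,
              search_n2 = search_n2 %||% def$search_n2,
              search_p2 = search_p2 %||% def$search_p2,
              pre_presence_ms = pre_presence_ms)
  stopifnot(out$snr_roi[1] > 0, out$snr_roi[2] <= 2000,
            out$search_n2[1] > 0, out$search_p2[2] <= 2000,
            out$search_p2[1] >= out$search_n2[1])
  structure(out, class = "noxep_roi")
}

# Indices of samples with t (ms) in [lo, hi) on the epoch axis.
window_idx <- function(time_ms, lo, hi) which(time_ms >= lo & time_ms < hi)

#' Session signal-to-noise ratio in dB
#'
#' `20 * log10(RMS(region of interest) / RMS(pre-trigger second))` on the
#' averaged vertex trace; the voltage-dB convention (equivalently
#' `10 * log10` of the power ratio). Sessions below 3 dB are excluded by
#' [extract_session()].
#'
#' @param trace averaged trace spanning \[-1, 2) s.
#' @param fs sample rate, Hz.
#' @param roi a [roi_windows()].
#' @return SNR in dB.
#' @export
session_snr <- function(trace, fs, roi) {
  stopifnot(inherits(roi, "noxep_roi"), length(trace) == 3 * fs)
  t_ms <- epoch_time(fs) * 1000
  pre <- rms(trace[window_idx(t_ms, -1000, 0)])
  if (pre == 0) stop("degenerate input: zero pre-trigger RMS")
  sig <- rms(trace[window_idx(t_ms, roi$snr_roi[1], roi$snr_roi[2])])
  20 * log10(sig / pre)
}

# Component presence rule: the peak must exceed sqrt(2) x the RMS of the
# 500 ms immediately pre-trigger (a 3 dB margin, consistent with the
# session gate). The multiplier is configurable.
presence_threshold <- function(trace, fs, pre_ms = 500, multiplier = sqrt(2)) {
  t_ms <- epoch_time(fs) * 1000
  multiplier * rms(trace[window_idx(t_ms, -pre_ms, 0)])
}

#' Detect the vertex N2 and P2 components
#'
#' N2 is the most negative sample within its search window; P2 the most
#' positive sample within its window constrained to times after the N2
#' peak. A component is marked present when its peak magnitude reaches the
#' presence threshold; absent components carry amplitude 0 and a missing
#' latency.
#'
#' @param trace averaged vertex trace spanning \[-1, 2) s.
#' @param fs sample rate, Hz.
#' @param roi a [roi_windows()].
#' @param multiplier presence-rule multiplier on the 500 ms pre-trigger RMS.
#' @return list with `n2` and `p2`, each `(present, latency_ms,
#'   amplitude_uv)`.
#' @export
detect_vertex_components <- function(trace, fs, roi, multiplier = sqrt(2)) {
  stopifnot(inherits(roi, "noxep_roi"), length(trace) == 3 * fs)
  t_ms <- epoch_time(fs) * 1000
  thr <- presence_threshold(trace, fs, roi$pre_presence_ms, multiplier)
  absent <- list(present = FALSE, latency_ms = NA_real_, amplitude_uv = 0)

  w2 <- window_idx(t_ms, roi$search_n2[1], roi$search_n2[2])
  i2 <- w2[which.min(trace[w2])]
  n2 <- if (abs(trace[i2]) >= thr) {
    list(present = TRUE, latency_ms = t_ms[i2], amplitude_uv = trace[i2])
  } else absent

  wp <- window_idx(t_ms, roi$search_p2[1], roi$search_p2[2])
  if (n2$present) wp <- wp[t_ms[wp] > n2$latency_ms]
  p2 <- if (length(wp) == 0) absent else {
    ip <- wp[which.max(trace[wp])]
    if (abs(trace[ip]) >= thr) {
      list(present = TRUE, latency_ms = t_ms[ip], amplitude_uv = trace[ip])
    } else absent
  }
  list(n2 = n2, p2 = p2)
}

#' Onset of the N2 component on the vertex trace
#'
#' Operationalized as the last crossing of a fraction of the N2 peak
#' amplitude before the N2 peak. The default fraction is 0.5
#' (half-amplitude onset): with canonical laser component geometry the N1
#' peak overlaps the shallow early tail of N2, so a near-zero (10%)
#' crossing would place the "onset" before the N1 peak itself and
#' misclassify textbook N1 waveforms as absent.
#'
#' @param trace averaged vertex trace.
#' @param fs sample rate, Hz.
#' @param n2 the N2 entry from [detect_vertex_components()].
#' @param fraction fraction of the N2 amplitude defining the onset
#'   crossing.
#' @param floor_ms fallback/lower bound for the onset, ms.
#' @return onset time in ms.
#' @export
n2_onset <- function(trace, fs, n2, fraction = 0.5, floor_ms = 0) {
  stopifnot(n2$present)
  t_ms <- epoch_time(fs) * 1000
  i_peak <- which.min(abs(t_ms - n2$latency_ms))
  level <- fraction * abs(n2$amplitude_uv)
  pre <- which(t_ms < n2$latency_ms & t_ms >= floor_ms)
  above <- pre[trace[pre] > -level]        # N2 is negative-going
  if (length(above) == 0) return(floor_ms)
  t_ms[max(above)]
}

#' Detect the contralateral N1 component
#'
#' N1 is the most negative sample on the contralateral montage between the
#' start of the SNR region of interest and the onset of N2; its latency
#' must precede the N2 onset by construction. Reported absent when N2 is
#' absent, when the window is degenerate, or when the peak fails the
#' presence rule.
#'
#' @param trace averaged contralateral trace spanning \[-1, 2) s.
#' @param fs sample rate, Hz.
#' @param roi a [roi_windows()].
#' @param n2 the N2 entry from [detect_vertex_components()] (vertex trace).
#' @param n2_onset_ms onset from [n2_onset()].
#' @param multiplier presence-rule multiplier.
#' @return `(present, latency_ms, amplitude_uv)`.
#' @export
detect_n1 <- function(trace, fs, roi, n2, n2_onset_ms,
                      multiplier = sqrt(2)) {
  absent <- list(present = FALSE, latency_ms = NA_real_, amplitude_uv = 0)
  if (!isTRUE(n2$present)) return(absent)
  t_ms <- epoch_time(fs) * 1000
  w <- window_idx(t_ms, roi$snr_roi[1], n2_onset_ms)
  if (length(w) == 0) return(absent)
  thr <- presence_threshold(trace, fs, roi$pre_presence_ms, multiplier)
  i1 <- w[which.min(trace[w])]
  # a minimum on the window's closing edge is the tail of a later
  # negativity, not a peak preceding the N2 onset
  if (i1 == w[length(w)]) return(absent)
  if (trace[i1] < 0 && abs(trace[i1]) >= thr) {
    list(present = TRUE, latency_ms = t_ms[i1], amplitude_uv = trace[i1])
  } else absent
}

#' Extract a session's evoked-potential result
#'
#' Full extraction chain on an epoch set: baseline correction (if still
#' pending), amplitude-criterion artifact rejection, montage derivation,
#' averaging of the non-rejected epochs, the 3 dB session SNR gate on the
#' averaged vertex trace, and rule-based N1/N2/P2 marking. Excluded
#' sessions (SNR below the gate) carry their SNR and flag but no component
#' values. N2P2 is the peak-to-peak amplitude `P2 - N2` when both are
#' present, 0 otherwise; absent components carry amplitude 0 and a missing
#' latency.
#'
#' @param es an [epoch_set()].
#' @param modality `"chep"` or `"lep"`.
#' @param stimulated_side `"left"` or `"right"`.
#' @param snr_gate_db exclusion threshold, dB.
#' @param rejection_uv artifact criterion, microvolts.
#' @param presence_multiplier presence-rule multiplier.
#' @param roi optional [roi_windows()] override.
#' @param onset_fraction fraction for [n2_onset()].
#' @return object of class `noxep_ep_result`.
#' @export
extract_session <- function(es, modality = c("chep", "lep"),
                            stimulated_side = "left",
                            snr_gate_db = 3, rejection_uv = 150,
                            presence_multiplier = sqrt(2),
                            roi = NULL, onset_fraction = 0.5) {
  modality <- match.arg(modality)
  stopifnot(inherits(es, "noxep_epochs"))
  roi <- roi %||% roi_windows(modality)
  fs <- es$sample_rate
  es <- baseline_correct(es)
  es <- reject_artifacts(es, rejection_uv)
  mont <- derive_montages(es, stimulated_side)
  vertex <- average_epochs(mont$vertex, mont$rejected)
  contra <- average_epochs(mont$contralateral, mont$rejected)
  n_avg <- dim(es$data)[1] - length(es$rejected)
  snr <- session_snr(vertex, fs, roi)
  res <- list(modality = modality, session_snr_db = snr,
              session_excluded = snr < snr_gate_db,
              n_epochs_averaged = n_avg,
              n1 = NULL, n2 = NULL, p2 = NULL, n2p2_amplitude = NA_real_,
              roi = roi)
  if (!res$session_excluded) {
    vx <- detect_vertex_components(vertex, fs, roi, presence_multiplier)
    res$n2 <- vx$n2
    res$p2 <- vx$p2
    if (vx$n2$present) {
      onset <- n2_onset(vertex, fs, vx$n2, onset_fraction,
                        floor_ms = roi$snr_roi[1])
      res$n1 <- detect_n1(contra, fs, roi, vx$n2, onset,
                          presence_multiplier)
    } else {
      res$n1 <- list(present = FALSE, latency_ms = NA_real_,
                     amplitude_uv = 0)
    }
    res$n2p2_amplitude <- if (vx$n2$present && vx$p2$present)
      vx$p2$amplitude_uv - vx$n2$amplitude_uv else 0
  }
  structure(res, class = "noxep_ep_result")
}

#' Run the preprocessing and extraction chain on a continuous recording
#'
#' Convenience wrapper: [bandpass()] (1-40 Hz), [epoch_recording()], then
#' [extract_session()].
#'
#' @param rec a `noxep_recording`.
#' @param ... passed to [extract_session()].
#' @inheritParams extract_session
#' @return a `noxep_ep_result`.
#' @export
extract_recording <- function(rec, modality, stimulated_side = "left", ...) {
  rec <- bandpass(rec)
  es <- epoch_recording(rec)
  extract_session(es, modality, stimulated_side, ...)
}

#' @export
print.noxep_ep_result <- function(x, ...) {
  cat(sprintf("<EP result> %s, SNR %.1f dB%s, %d epochs averaged\n",
              toupper(x$modality), x$session_snr_db,
              if (x$session_excluded) " (EXCLUDED)" else "",
              x$n_epochs_averaged))
  if (!x$session_excluded) {
    for (nm in c("n1", "n2", "p2")) {
      c_ <- x[[nm]]
      cat(sprintf("  %s: %s\n", toupper(nm),
                  if (c_$present)
                    sprintf("%.1f uV @ %.1f ms", c_$amplitude_uv,
                            c_$latency_ms)
                  else "absent (0 uV)"))
    }
    cat(sprintf("  N2P2: %.1f uV\n", x$n2p2_amplitude))
  }
  invisible(x)
}

#' One-row data frame of an extraction result
#'
#' Layout used by the session-level comparison reports: SNR, exclusion
#' flag, per-component latency and amplitude, and N2P2.
#'
#' @param x a `noxep_ep_result`.
#' @param ... unused.
#' @export
as.data.frame.noxep_ep_result <- function(x, ...) {
  comp_cols <- function(nm) {
    c_ <- x[[nm]]
    if (is.null(c_)) {
      out <- list(NA, NA_real_, NA_real_)
    } else {
      out <- list(c_$present, c_$latency_ms, c_$amplitude_uv)
    }
    stats::setNames(out, paste0(nm, c("_present", "_latency", "_amplitude")))
  }
  data.frame(modality = x$modality,
             snr_db = x$session_snr_db,
             excluded = x$session_excluded,
             n_epochs = x$n_epochs_averaged,
             comp_cols("n1"), comp_cols("n2"), comp_cols("p2"),
             n2p2_amplitude = x$n2p2_amplitude)
}
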