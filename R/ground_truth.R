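#' Evoked-potential ground truth
#'
#' Parameterizes the three canonical nociceptive EP components as Gaussian
#' bumps `A * exp(-(t - L)^2 / (2 * sd^2))` with trial-to-trial latency
#' jitter, embedded in 1/f^beta background noise. N1 is injected on the
#' contralateral central electrode (C4 for left-arm stimulation); N2 and P2
#' on the vertex electrode Cz. Reference channels (A1, A2 behind the ears)
#' and Fz carry noise only by default, so the vertex (Cz - mean(A1, A2)) and
#' contralateral (C3/C4 - Fz) montages recover the injected components.
#'
#' @param n1,n2,p2 named lists with `latency_ms`, `amplitude_uv`,
#'   `width_sd_ms`. N1 and N2 amplitudes must be negative, P2 positive, and
#'   latencies strictly ordered N1 < N2 < P2.
#' @param latency_jitter_sd_ms SD of the per-trial latency jitter, ms.
#' @param noise_rms_uv RMS of the background noise per channel, microvolts
#'   (0 gives a noiseless template).
#' @param noise_exponent spectral exponent beta of the 1/f^beta background.
#' @param n1_channel channel carrying N1 (the electrode contralateral to the
#'   stimulated arm).
#' @param vertex_channel channel carrying N2 and P2.
#' @return object of class `noxep_truth`.
#' @export
ep_ground_truth <- function(n1 = list(latency_ms = 175, amplitude_uv = -7.1,
                                      width_sd_ms = 15),
                            n2 = list(latency_ms = 211, amplitude_uv = -18.9,
                                      width_sd_ms = 25),
                            p2 = list(latency_ms = 322, amplitude_uv = 16.8,
                                      width_sd_ms = 40),
                            latency_jitter_sd_ms = 10,
                            noise_rms_uv = 10,
                            noise_exponent = 1,
                            n1_channel = "C4",
                            vertex_channel = "Cz") {
  comp <- list(N1 = n1, N2 = n2, P2 = p2)
  for (nm in names(comp)) {
    c_ <- comp[[nm]]
    stopifnot(all(c("latency_ms", "amplitude_uv", "width_sd_ms") %in% names(c_)),
              c_$width_sd_ms > 0, c_$latency_ms > 0)
  }
  if (!(n1$latency_ms < n2$latency_ms && n2$latency_ms < p2$latency_ms))
    stop("component latencies must satisfy N1 < N2 < P2")
  if (n1$amplitude_uv >= 0 || n2$amplitude_uv >= 0)
    stop("N1 and N2 amplitudes must be negative")
  if (p2$amplitude_uv <= 0) stop("P2 amplitude must be positive")
  stopifnot(latency_jitter_sd_ms >= 0, noise_rms_uv >= 0)
  structure(
    list(components = comp,
         latency_jitter_sd_ms = latency_jitter_sd_ms,
         noise_rms_uv = noise_rms_uv,
         noise_exponent = noise_exponent,
         channel_map = list(N1 = n1_channel, N2 = vertex_channel,
                            P2 = vertex_channel)),
    class = "noxep_truth")
}

#' Baseline component calibrations per modality
#'
#' Default ground-truth calibrations for the two stimulation modalities:
#' contact heat (`"chep"`: N1 -3.6 uV at 336 ms, N2 -10.6 uV at 392 ms,
#' P2 13.0 uV at 494 ms) and laser (`"lep"`: N1 -7.1 uV at 175 ms,
#' N2 -18.9 uV at 211 ms, P2 16.8 uV at 322 ms), with the corresponding
#' between-subject SDs used by [sample_ground_truth()]. Component width SDs
#' (N1 15, N2 25, P2 40 ms) are a package choice: the waveshape is Gaussian
#' so that latency and amplitude ground truth are unambiguous.
#'
#' @param modality `"chep"` or `"lep"`.
#' @param ... overrides passed to [ep_ground_truth()].
#' @return object of class `noxep_calibration`: the population means (a
#'   `noxep_truth`) plus between-subject SDs.
#' @export
default_calibration <- function(modality = c("chep", "lep"), ...) {
  modality <- match.arg(modality)
  if (modality == "chep") {
    truth <- ep_ground_truth(
      n1 = list(latency_ms = 336, amplitude_uv = -3.6, width_sd_ms = 15),
      n2 = list(latency_ms = 392, amplitude_uv = -10.6, width_sd_ms = 25),
      p2 = list(latency_ms = 494, amplitude_uv = 13.0, width_sd_ms = 40),
      ...)
    sds <- list(N1 = c(latency = 33, amplitude = 2.5),
                N2 = c(latency = 37, amplitude = 6.3),
                P2 = c(latency = 49, amplitude = 7.4))
  } else {
    truth <- ep_ground_truth(
      n1 = list(latency_ms = 175, amplitude_uv = -7.1, width_sd_ms = 15),
      n2 = list(latency_ms = 211, amplitude_uv = -18.9, width_sd_ms = 25),
      p2 = list(latency_ms = 322, amplitude_uv = 16.8, width_sd_ms = 40),
      ...)
    sds <- list(N1 = c(latency = 23, amplitude = 4.5),
                N2 = c(latency = 19, amplitude = 8.6),
                P2 = c(latency = 26, amplitude = 7.2))
  }
  structure(list(modality = modality, mean = truth, sd = sds),
            class = "noxep_calibration")
}

#' Draw one subject's ground truth from a population calibration
#'
#' Between-subject latency variation is carried by one common latent factor
#' per subject: every component latency is `mean + sd * z` with a shared
#' `z ~ N(0, 1)`, so subjects shift their whole waveform together (the
#' conduction-speed picture). This keeps each component's marginal
#' distribution exactly at the calibrated mean and SD while preserving the
#' N1 < N2 < P2 order without rejection sampling, which would otherwise
#' bias the population means. Amplitudes are drawn independently per
#' component from the calibrated normals, truncated to the correct sign
#' with magnitude at least 1 uV (a detectable component must exist); the
#' truncation shifts the amplitude means by well under the calibrated SDs.
#'
#' @param calibration a [default_calibration()] (or compatible list).
#' @param seed optional seed.
#' @return a `noxep_truth` for one simulated subject/session.
#' @export
sample_ground_truth <- function(calibration, seed = NULL) {
  stopifnot(inherits(calibration, "noxep_calibration"))
  maybe_seed(seed)
  mu <- calibration$mean
  z <- stats::rnorm(1)
  d <- list()
  for (nm in c("N1", "N2", "P2")) {
    m <- mu$components[[nm]]
    s <- calibration$sd[[nm]]
    neg <- m$amplitude_uv < 0
    amp <- stats::rnorm(1, m$amplitude_uv, s[["amplitude"]])
    tries <- 0
    while (((neg && amp > -1) || (!neg && amp < 1)) && tries < 1000) {
      amp <- stats::rnorm(1, m$amplitude_uv, s[["amplitude"]])
      tries <- tries + 1
    }
    d[[nm]] <- list(latency_ms = m$latency_ms + s[["latency"]] * z,
                    amplitude_uv = amp,
                    width_sd_ms = m$width_sd_ms)
  }
  # the common factor keeps ordering for any plausible z; guard regardless
  if (!(d$N1$latency_ms < d$N2$latency_ms &&
        d$N2$latency_ms < d$P2$latency_ms))
    stop("calibration SDs too large for a common latency factor")
  ep_ground_truth(n1 = d$N1, n2 = d$N2, p2 = d$P2,
                  latency_jitter_sd_ms = mu$latency_jitter_sd_ms,
                  noise_rms_uv = mu$noise_rms_uv,
                  noise_exponent = mu$noise_exponent,
                  n1_channel = mu$channel_map$N1,
                  vertex_channel = mu$channel_map$N2)
}
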