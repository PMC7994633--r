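test_that("session SNR follows the voltage-dB convention", {
  fs <- fs_test
  roi <- roi_windows("lep")
  # piecewise trace: unit RMS pre-trigger, controlled RMS inside the ROI
  base <- trace_from(function(t) if (t < 0) 1 else 0)
  roi_part <- trace_from(function(t) if (t >= 150 && t < 550) 1 else 0)
  expect_equal(session_snr(base + 2 * roi_part, fs, roi),
               20 * log10(2), tolerance = 1e-9)          # 6.02 dB
  expect_equal(session_snr(base + 1 * roi_part, fs, roi), 0)
  expect_equal(session_snr(base + sqrt(2) * roi_part, fs, roi),
               10 * log10(2), tolerance = 1e-9)          # 3.01 dB
  expect_error(session_snr(roi_part, fs, roi), "zero pre-trigger")
})

test_that("vertex detection equals a brute-force scan over the windows", {
  fs <- fs_test
  roi <- roi_windows("chep")
  set.seed(33)
  for (i in 1:8) {
    trace <- pink_noise(3 * fs, beta = 1, fs = fs, rms = 4)
    got <- detect_vertex_components(trace, fs, roi, multiplier = 0)
    ref_n2 <- brute_extremum(trace, roi$search_n2[1], roi$search_n2[2],
                             fs, "min")
    expect_equal(got$n2$latency_ms, ref_n2$latency_ms)
    expect_equal(got$n2$amplitude_uv, ref_n2$amplitude_uv)
    ref_p2 <- brute_extremum(trace, max(roi$search_p2[1],
                                        ref_n2$latency_ms + 0.001),
                             roi$search_p2[2], fs, "max")
    expect_equal(got$p2$latency_ms, ref_p2$latency_ms)
    expect_equal(got$p2$amplitude_uv, ref_p2$amplitude_uv)
  }
})

test_that("noiseless canonical templates are recovered exactly", {
  fs <- fs_test
  # contact-heat template: N2 -10.6 uV @ 392 ms, P2 13.0 uV @ 494 ms
  comps <- list(list(latency_ms = 392, amplitude_uv = -10.6,
                     width_sd_ms = 25),
                list(latency_ms = 494, amplitude_uv = 13.0,
                     width_sd_ms = 40))
  trace <- analytic_template(comps, fs)
  got <- detect_vertex_components(trace, fs, roi_windows("chep"),
                                  multiplier = 0)
  # against the analytic template's own extrema (sample-exact)
  ref_n2 <- brute_extremum(trace, 300, 500, fs, "min")
  expect_equal(got$n2$latency_ms, ref_n2$latency_ms)
  # against the nominal parameters: the N2-P2 overlap shifts each peak by
  # the other's tail (up to ~5% in amplitude, ~3 ms in latency here)
  expect_lt(abs(got$n2$latency_ms - 392), 3)
  expect_lt(abs(got$n2$amplitude_uv - (-10.6)) / 10.6, 0.06)
  expect_lt(abs(got$p2$latency_ms - 494), 3)
  expect_lt(abs(got$p2$amplitude_uv - 13.0) / 13.0, 0.06)
})

test_that("sub-threshold waveforms are declared absent with 0 uV", {
  fs <- fs_test
  set.seed(9)
  noise_pre <- trace_from(function(t) 0) +
    c(pink_noise(fs, beta = 1, fs = fs, rms = 3), numeric(2 * fs))
  got <- detect_vertex_components(noise_pre, fs, roi_windows("chep"))
  expect_false(got$n2$present)
  expect_false(got$p2$present)
  expect_identical(got$n2$amplitude_uv, 0)
  expect_identical(got$p2$amplitude_uv, 0)
  expect_true(is.na(got$n2$latency_ms))
  # a bump below sqrt(2) x RMS(pre 500 ms) stays absent
  thr <- noxep:::presence_threshold(noise_pre, fs)
  small <- noise_pre + analytic_template(
    list(list(latency_ms = 400, amplitude_uv = -0.5 * thr,
              width_sd_ms = 25)), fs)
  expect_false(detect_vertex_components(small, fs,
                                        roi_windows("chep"))$n2$present)
})

test_that("N1 marking requires an N2 and precedence of the N2 onset", {
  fs <- fs_test
  roi <- roi_windows("lep")
  vertex <- analytic_template(
    list(list(latency_ms = 211, amplitude_uv = -18.9, width_sd_ms = 25),
         list(latency_ms = 322, amplitude_uv = 16.8, width_sd_ms = 40)), fs)
  contra <- analytic_template(
    list(list(latency_ms = 175, amplitude_uv = -7.1, width_sd_ms = 15)), fs)
  vx <- detect_vertex_components(vertex, fs, roi, multiplier = 0)
  onset <- n2_onset(vertex, fs, vx$n2, floor_ms = roi$snr_roi[1])
  expect_gt(onset, 175)                    # half-amplitude onset after N1
  expect_lt(onset, vx$n2$latency_ms)
  n1 <- detect_n1(contra, fs, roi, vx$n2, onset, multiplier = 0)
  expect_true(n1$present)
  expect_equal(n1$latency_ms, 175, tolerance = 0.3)
  expect_equal(n1$amplitude_uv, -7.1, tolerance = 0.01)
  expect_lt(n1$latency_ms, vx$n2$latency_ms)
  # N2 absent -> N1 absent by rule
  absent_n2 <- list(present = FALSE, latency_ms = NA_real_, amplitude_uv = 0)
  expect_false(detect_n1(contra, fs, roi, absent_n2, onset)$present)
  # an "N1" bump after the N2 onset is not accepted
  late <- analytic_template(
    list(list(latency_ms = onset + 20, amplitude_uv = -7.1,
              width_sd_ms = 10)), fs)
  expect_false(detect_n1(late, fs, roi, vx$n2, onset,
                         multiplier = 0.1)$present)
})

test_that("extract_session gates on SNR and composes the detectors", {
  tr <- default_calibration("chep")$mean    # population-mean ground truth
  es <- synthesize_session(tr, stimulus_train("contact_heat", 20),
                           continuous = FALSE, seed = 6)
  ep <- extract_session(es, "chep")
  expect_false(ep$session_excluded)
  expect_true(ep$n2$present)
  expect_true(ep$p2$present)
  expect_equal(ep$n_epochs_averaged, 20)
  expect_equal(ep$n2p2_amplitude,
               ep$p2$amplitude_uv - ep$n2$amplitude_uv)
  # inflate the noise so the session falls under the 3 dB gate
  noisy <- ep_ground_truth(
    n1 = tr$components$N1, n2 = tr$components$N2, p2 = tr$components$P2,
    noise_rms_uv = 400, noise_exponent = 0)
  es2 <- synthesize_session(noisy, stimulus_train("contact_heat", 20),
                            continuous = FALSE, seed = 6)
  ep2 <- extract_session(es2, "chep", rejection_uv = Inf)
  expect_true(ep2$session_excluded)
  expect_lt(ep2$session_snr_db, 3)
  # excluded sessions report no components
  expect_null(ep2$n2)
  df <- as.data.frame(ep2)
  expect_true(is.na(df$n2_latency) && is.na(df$n2_amplitude))
})

test_that("averaging identity: one noiseless epoch equals the 20-epoch average", {
  tr <- separated_truth(noise_rms = 0, jitter = 0)
  es20 <- synthesize_session(tr, stimulus_train("laser", 20),
                             continuous = FALSE, seed = 1)
  es20 <- baseline_correct(es20)
  m <- derive_montages(es20, "left")
  avg20 <- average_epochs(m$vertex)
  single <- m$vertex[1, ]
  expect_equal(avg20, single, tolerance = 1e-12)
  fs <- fs_test
  got1 <- detect_vertex_components(single, fs, roi_windows("chep"),
                                   multiplier = 0)
  got20 <- detect_vertex_components(avg20, fs, roi_windows("chep"),
                                    multiplier = 0)
  expect_identical(got1, got20)
})

test_that("component order holds whenever all three are present", {
  df <- recovery_experiment("lep", n_sessions = 6, seed = 3,
                            continuous = FALSE)
  all3 <- df[df$n1_present & df$n2_present & df$p2_present, ]
  if (nrow(all3) > 0) {
    expect_true(all(all3$n1_latency < all3$n2_latency))
    expect_true(all(all3$n2_latency < all3$p2_latency))
  }
  expect_true(all(!df$excluded | is.na(df$n2_latency)))
})
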