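# Build a bare recording from a channels x samples matrix.
make_recording <- function(dat, fs, triggers, channels = rownames(dat)) {
  structure(list(data = dat, sample_rate = fs, channel_labels = channels,
                 trigger_samples = as.integer(triggers),
                 ground_truth = NULL, provenance = list()),
            class = "noxep_recording")
}

test_that("the designed bandpass meets its frequency-response contract", {
  fs <- 4000
  taps <- design_bandpass(fs)
  H <- function(f) abs(sum(taps * exp(-2i * pi * f * seq_along(taps) / fs)))
  # passband flat to < 1% between 2 and 35 Hz
  for (f in c(2, 5, 10, 20, 35)) expect_lt(abs(H(f) - 1), 0.01)
  # >= 20 dB attenuation outside the band
  expect_lt(H(0.25), 0.1)
  expect_lt(H(60), 0.1)
})

test_that("sines pass through the filter per the tap-derived response", {
  fs <- 1000
  taps <- design_bandpass(fs)
  H <- function(f) abs(sum(taps * exp(-2i * pi * f * seq_along(taps) / fs)))
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  mid <- seq(20 * fs, 40 * fs)             # away from edge transients
  y10 <- noxep:::fir_zerophase(sin(2 * pi * 10 * t), taps)
  expect_equal(max(abs(y10[mid])), H(10), tolerance = 0.01)
  expect_equal(max(abs(y10[mid])), 1.0, tolerance = 0.01)
  y60 <- noxep:::fir_zerophase(sin(2 * pi * 60 * t), taps)
  expect_lte(max(abs(y60[mid])), 0.1)
  ydc <- noxep:::fir_zerophase(rep(100, length(t)), taps)
  expect_lt(abs(mean(ydc[mid])), 1)        # DC is outside the passband
})

test_that("filtering refuses signals shorter than the filter", {
  taps <- design_bandpass(4000)
  expect_error(noxep:::fir_zerophase(numeric(5000), taps), "shorter")
})

test_that("epoching does exact index arithmetic and baseline correction", {
  fs <- 4000
  ramp <- matrix(rep(seq_len(12 * fs), each = 2), nrow = 2, byrow = FALSE,
                 dimnames = list(c("Cz", "Fz"), NULL))
  ramp <- rbind(ramp, matrix(5, nrow = 1, ncol = ncol(ramp),
                             dimnames = list("A1", NULL)))
  rec <- make_recording(ramp, fs, triggers = 5 * fs + 1)
  es <- epoch_recording(rec)
  expect_equal(dim(es$data), c(1, 3, 3 * fs))
  # trigger at sample 20001 covers samples [16001, 32000]; the ramp value
  # minus its pre-trigger mean is t * fs + (fs + 1) / 2 in samples
  raw <- seq(5 * fs + 1 - fs, 5 * fs + 2 * fs)
  expect_equal(es$data[1, "Cz", ], raw - mean(raw[1:fs]))
  # constant channel is identically zero after baseline correction
  expect_equal(max(abs(es$data[1, "A1", ])), 0)
  expect_true(es$baseline_corrected)
})

test_that("every clean trigger yields one epoch; edge triggers are skipped", {
  fs <- 500
  n <- 300 * fs
  dat <- matrix(0, nrow = 1, ncol = n, dimnames = list("Cz", NULL))
  trig <- as.integer(seq(2 * fs, by = 10 * fs, length.out = 20))
  rec <- make_recording(dat, fs, trig)
  expect_equal(dim(epoch_recording(rec)$data)[1], 20)
  rec_bad <- make_recording(dat, fs, c(100L, trig, n - 100L))
  expect_warning(es <- epoch_recording(rec_bad), "skipped")
  expect_equal(dim(es$data)[1], 20)
})

test_that("artifact rejection marks, never deletes, offending epochs", {
  tr <- separated_truth(noise_rms = 5)
  es <- synthesize_session(tr, stimulus_train("laser", 10),
                           continuous = FALSE, seed = 4)
  es <- baseline_correct(es)
  clean <- reject_artifacts(es, 150)
  expect_length(clean$rejected, 0)          # generator stays well below
  spiked <- es
  spiked$data[4, "Cz", 6000] <- 500
  out <- reject_artifacts(spiked, 150)
  expect_identical(out$rejected, 4L)
  expect_equal(dim(out$data)[1], 10)        # epoch retained in container
  expect_length(reject_artifacts(spiked, Inf)$rejected, 0)
  allbad <- es
  allbad$data[, "Cz", 6000] <- 1e4
  expect_error(reject_artifacts(allbad, 150), "unusable")
})

test_that("montage derivation implements the reference scheme", {
  tr <- separated_truth(noise_rms = 0)
  es <- synthesize_session(tr, stimulus_train("laser", 3),
                           continuous = FALSE, seed = 1)
  es <- baseline_correct(es)
  m_left <- derive_montages(es, "left")
  # N1 was injected on C4; left-side stimulation reads C4 - Fz
  t_ms <- noxep:::epoch_time(4000) * 1000
  avg_c <- average_epochs(m_left$contralateral)
  expect_equal(t_ms[which.min(avg_c)], 150)
  # N2 injected only at Cz: vertex minimum at the N2 latency
  avg_v <- average_epochs(m_left$vertex)
  post <- which(t_ms > 0 & t_ms < 400)
  expect_equal(t_ms[post[which.min(avg_v[post])]], 300)
  # right-side stimulation reads C3, which carries no component here
  m_right <- derive_montages(es, "right")
  expect_equal(max(abs(average_epochs(m_right$contralateral))), 0)
  # identical Cz/A1/A2 traces cancel exactly
  es2 <- es
  es2$data[, "A1", ] <- es2$data[, "Cz", ]
  es2$data[, "A2", ] <- es2$data[, "Cz", ]
  expect_equal(max(abs(derive_montages(es2, "left")$vertex)), 0)
  # missing channels are named in the error
  es3 <- es
  dimnames(es3$data)[[2]][dimnames(es3$data)[[2]] == "A1"] <- "X1"
  es3$channel_labels <- dimnames(es3$data)[[2]]
  expect_error(derive_montages(es3, "left"), "A1")
})

test_that("filtering commutes with epoch extraction away from the edges", {
  fs <- 500
  set.seed(12)
  n <- 60 * fs
  x <- pink_noise(n, beta = 1, fs = fs, rms = 5)
  dat <- matrix(x, nrow = 1, dimnames = list("Cz", NULL))
  taps <- design_bandpass(fs)
  trig <- 30 * fs
  # filter the full record, then cut the epoch
  full <- noxep:::fir_zerophase(x, taps)
  ep_full <- full[(trig - fs):(trig + 2 * fs - 1)]
  # filter a generous sub-record around the same trigger, then cut
  margin <- length(taps)
  sub <- x[(trig - fs - margin):(trig + 2 * fs - 1 + margin)]
  ep_sub <- noxep:::fir_zerophase(sub, taps)[(margin + 1):(margin + 3 * fs)]
  expect_equal(ep_sub, ep_full, tolerance = 1e-6)
})

test_that("averaging shrinks background noise like 1/sqrt(n)", {
  fs <- 500
  set.seed(21)
  ratios <- replicate(6, {
    epochs <- t(replicate(20, pink_noise(3 * fs, beta = 1, fs = fs,
                                         rms = 3)))
    r5 <- noxep:::rms(colMeans(epochs[1:5, ]))
    r20 <- noxep:::rms(colMeans(epochs))
    (r5 / r20) / sqrt(20 / 5)
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
})
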