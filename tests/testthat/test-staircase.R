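test_that("familiarization target discards the first stimulus", {
  expect_equal(familiarization_target(c(9, rep(3, 10)))$target_nrs, 3.0)
  expect_equal(familiarization_target(c(5, rep(0, 10)))$target_nrs, 0.0)
  expect_equal(
    familiarization_target(c(1, 1, 2, 3, 4, 5, 4, 3, 2, 1, 4))$target_nrs,
    2.9)
  expect_error(familiarization_target(rep(3, 10)), "exactly 11")
})

test_that("the energy update rule follows the staircase contract", {
  expect_equal(next_energy(1.5, 0, 3), 2.0)     # no pain: large step up
  expect_equal(next_energy(2.0, 2, 3), 2.25)    # below target: small up
  expect_equal(next_energy(2.25, 4, 3), 2.0)    # above target: small down
  expect_equal(next_energy(2.0, 3, 3), 2.0)     # at target: hold
  expect_equal(next_energy(2.0, 3, 3, tie = "down"), 1.75)
  expect_message(out <- next_energy(4.9, 0, 3, energy_cap = 5), "cap")
  expect_equal(out, 5)
  expect_message(out <- next_energy(0.3, 9, 3), "floor")
  expect_equal(out, 0.25)
})

test_that("a scripted rating sequence reproduces the hand-simulated trajectory", {
  # hand-derived with the update rule, target 3, start 1.5 J:
  # ratings 0,0,2,4,2,4,3,3,3,3 give
  # 1.5 -> 2.0 -> 2.5 -> 2.75 -> 2.5 -> 2.75 -> 2.5 (hold to the end)
  script <- c(0, 0, 2, 4, 2, 4, 3, 3, 3, 3)
  expected <- c(1.5, 2.0, 2.5, 2.75, 2.5, 2.75, 2.5, 2.5, 2.5, 2.5)
  calls <- new.env(); calls$n <- c(A = 0L, B = 0L)
  cb <- function(energy, staircase) {
    calls$n[[staircase]] <- calls$n[[staircase]] + 1L
    script[calls$n[[staircase]]]
  }
  m <- run_matching(cb, matching_target(3), seed = 5)
  for (sc in c("A", "B")) {
    tr <- m$trials[m$trials$staircase == sc, ]
    expect_equal(tr$energy, expected)
    expect_equal(tr$rating, script)
  }
  expect_equal(m$result$median_energy_A, 2.5)
  expect_equal(m$result$median_energy_B, 2.5)
  # median rating = 3 = target, so no correction
  expect_false(m$result$correction_applied)
  expect_equal(m$result$matched_energy, 2.5)
})

test_that("visited energies stay on the 0.25 J grid, matched on 0.125 J", {
  for (s in 1:10) {
    obs <- observer(pain_threshold_energy = runif(1, 0.5, 2),
                    slope = runif(1, 1, 4), rating_noise_sd = runif(1, 0, 1))
    m <- run_matching(obs, matching_target(runif(1, 1, 6)), seed = s)
    offs <- (m$trials$energy - 1.5) / 0.25
    expect_equal(offs, round(offs), tolerance = 1e-9)
    # each median sits on the 0.125 J grid (mean of two 0.25 J values);
    # their average therefore sits on the 0.0625 J grid
    for (med in c(m$result$median_energy_A, m$result$median_energy_B)) {
      g <- med / 0.125
      expect_equal(g, round(g), tolerance = 1e-9)
    }
    mg <- m$result$matched_energy / 0.0625
    expect_equal(mg, round(mg), tolerance = 1e-9)
    # both staircases deliver their full 10 stimuli
    expect_equal(as.integer(table(m$trials$staircase)), c(10L, 10L))
  }
})

test_that("interleaving never runs one staircase more than 3 trials in a row", {
  for (s in 1:20) {
    obs <- observer()
    m <- run_matching(obs, matching_target(3), seed = s)
    expect_lte(max(rle(m$trials$staircase)$lengths), 3)
  }
})

test_that("the +0.25 J correction never decreases the matched energy", {
  for (s in 1:10) {
    obs <- observer(rating_noise_sd = 1)
    m <- run_matching(obs, matching_target(4), seed = s)
    raw <- mean(c(m$result$median_energy_A, m$result$median_energy_B))
    expect_gte(m$result$matched_energy, raw)
    expect_equal(m$result$matched_energy - raw,
                 if (m$result$correction_applied) 0.25 else 0)
  }
})

test_that("the match result is invariant to the interleaving order", {
  # a noiseless observer rates deterministically from energy alone, so
  # each staircase's trajectory depends only on its own trial sequence
  obs <- observer(rating_noise_sd = 0)
  tg <- matching_target(3)
  results <- lapply(1:6, function(s) run_matching(obs, tg, seed = s)$result)
  for (r in results[-1]) expect_identical(r, results[[1]])
})

test_that("a noiseless monotone observer converges around the target energy", {
  obs <- observer(pain_threshold_energy = 1.0, slope = 2.5,
                  rating_noise_sd = 0)
  # tie = "down": ratings at the target step back down, so the staircase
  # oscillates within one small step around the bracketing energy
  m <- run_matching(obs, matching_target(3), seed = 2, tie = "down")
  for (sc in c("A", "B")) {
    e <- m$trials$energy[m$trials$staircase == sc]
    d <- diff(e); d <- d[d != 0]
    first_rev <- which(diff(sign(d)) != 0)[1]
    expect_false(is.na(first_rev))
    changes <- which(diff(e) != 0)
    tail_e <- e[(changes[first_rev + 1]):length(e)]
    expect_lte(max(tail_e) - min(tail_e), 0.25 + 1e-9)
    expect_false(m$result$nonconverged[[sc]])
  }
  # tie = "hold" (default): the staircase locks at the first energy whose
  # rating equals the target and is flagged as reversal-free
  mh <- run_matching(obs, matching_target(3), seed = 2)
  for (sc in c("A", "B")) {
    e <- mh$trials$energy[mh$trials$staircase == sc]
    expect_equal(e[length(e)], 2.25)        # 2.5 NRS/J * 1.25 J rounds to 3
    expect_equal(mh$result[[paste0("median_energy_", sc)]], 2.25)
  }
})

test_that("a failing rating callback aborts with the partial trajectory", {
  boom <- function(energy) {
    if (energy > 2) stop("stimulator fault") else 0
  }
  err <- tryCatch(run_matching(boom, matching_target(3), seed = 1),
                  error = function(e) e)
  expect_s3_class(err, "noxep_matching_error")
  expect_match(conditionMessage(err), "stimulator fault")
  expect_true(is.data.frame(err$trajectory))
  expect_true(all(err$trajectory$energy <= 2))
})

test_that("grossly diverging staircases warn but still average", {
  # staircase A keeps rating 0 (climbs by 0.5), B rates far above target
  cb <- function(energy, staircase) if (staircase == "A") 0 else 9
  expect_warning(m <- run_matching(cb, matching_target(3), seed = 4),
                 "diverge")
  expect_true(m$result$diverged)
})
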