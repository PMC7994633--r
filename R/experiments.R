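#' Closed-loop intensity-matching experiment
#'
#' Validates the staircase matching loop on simulated observers: each
#' observer runs a contact-heat familiarization block (11 stimuli, first
#' discarded) to define its target, the double random staircase matches the
#' laser energy, and a 20-stimulus laser session at the matched energy
#' yields the matched-laser mean rating. Agreement between the per-subject
#' heat target and matched-laser mean NRS is summarized with ICC(A,2) and
#' Pearson r.
#'
#' @param n_subjects observers per replicate.
#' @param seed integer seed.
#' @param n_session stimuli in the laser session at matched energy.
#' @param ... cohort parameters passed to [simulate_cohort()].
#' @return list with `subjects` (per-subject table), `icc`, `pearson_r`.
#' @export
matching_experiment <- function(n_subjects = 20, seed = 1, n_session = 20,
                                ...) {
  observers <- simulate_cohort(n_subjects, seed = seed, ...)
  rows <- lapply(seq_along(observers), function(i) {
    obs <- observers[[i]]
    sseed <- child_seed(seed, 1000 + i)
    fam <- simulate_heat_session(obs, familiarization_train(),
                                 seed = child_seed(sseed, 1))
    target <- familiarization_target(fam)
    match <- run_matching(obs, target, seed = child_seed(sseed, 2))
    laser <- simulate_rating(obs, rep(match$result$matched_energy,
                                      n_session),
                             seed = child_seed(sseed, 3))
    data.frame(subject = obs$subject_id,
               target_nrs = target$target_nrs,
               matched_energy = match$result$matched_energy,
               matched_mean_nrs = mean(laser),
               correction_applied = match$result$correction_applied)
  })
  subjects <- do.call(rbind, rows)
  icc <- icc_a_k(cbind(subjects$target_nrs, subjects$matched_mean_nrs))
  r <- pearson_r(subjects$target_nrs, subjects$matched_mean_nrs)
  list(subjects = subjects, icc = icc$icc, pearson_r = r$r)
}

#' Component parameter-recovery experiment
#'
#' Generates seeded synthetic sessions from a population calibration (one
#' subject-level ground truth per session), pushes each through the
#' preprocessing and extraction chain, and tabulates recovered against
#' true component parameters. Continuous mode runs the full chain
#' including the FIR bandpass; epoched mode skips continuous filtering.
#'
#' @param modality `"chep"` or `"lep"`.
#' @param n_sessions number of sessions.
#' @param seed integer seed.
#' @param calibration population calibration (defaults to
#'   [default_calibration()] for the modality).
#' @param continuous generate continuous recordings (full chain) or epoch
#'   sets.
#' @param n_stimuli stimuli per session.
#' @return data frame with one row per session: session SNR, exclusion
#'   flag, recovered and true N1/N2/P2 latencies and amplitudes, and N2P2.
#' @export
recovery_experiment <- function(modality = c("chep", "lep"),
                                n_sessions = 100, seed = 1,
                                calibration = NULL, continuous = TRUE,
                                n_stimuli = 20) {
  modality <- match.arg(modality)
  calibration <- calibration %||% default_calibration(modality)
  train <- stimulus_train(if (modality == "chep") "contact_heat" else
                            "laser", n_stimuli)
  rows <- lapply(seq_len(n_sessions), function(i) {
    sseed <- child_seed(seed, 2000 + i)
    truth <- sample_ground_truth(calibration, seed = child_seed(sseed, 1))
    ses <- synthesize_session(truth, train, continuous = continuous,
                              seed = child_seed(sseed, 2))
    ep <- if (continuous) {
      extract_recording(ses, modality)
    } else {
      extract_session(ses, modality)
    }
    df <- as.data.frame(ep)
    truth_n2p2 <- truth$components$P2$amplitude_uv -
      truth$components$N2$amplitude_uv
    cbind(session = i, df,
          true_n1_latency = truth$components$N1$latency_ms,
          true_n1_amplitude = truth$components$N1$amplitude_uv,
          true_n2_latency = truth$components$N2$latency_ms,
          true_n2_amplitude = truth$components$N2$amplitude_uv,
          true_p2_latency = truth$components$P2$latency_ms,
          true_p2_amplitude = truth$components$P2$amplitude_uv,
          true_n2p2 = truth_n2p2)
  })
  do.call(rbind, rows)
}
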