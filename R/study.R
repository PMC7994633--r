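#' Study configuration
#'
#' Bundles every tunable of the end-to-end four-arm study
#' ({contact heat, laser} x {sham, capsaicin}): cohort size and seed,
#' generator calibrations per modality, analysis thresholds (3 dB session
#' gate, presence multiplier, artifact criterion) and the statistical
#' family (alpha 0.05 over 7 evoked-potential outcomes).
#'
#' @param n_subjects recruited cohort size.
#' @param seed master seed; every downstream draw derives from it.
#' @param dropout_subjects indices of pre-designated dropouts (recruited
#'   but excluded from all analyses, e.g. intolerant of familiarization).
#' @param calibrations list with `chep` and `lep` [default_calibration()]s.
#' @param snr_gate_db,presence_multiplier,rejection_uv analysis thresholds.
#' @param family_alpha,m_comparisons statistical family.
#' @param capsaicin_thermal_effect additive shift of the heat/laser rating
#'   mean under capsaicin, NRS (0: the null thermal finding).
#' @param capsaicin_ep_scale multiplicative change of component amplitudes
#'   under capsaicin (1: no effect).
#' @param simulate_eeg generate and analyse synthetic EEG (otherwise only
#'   ratings/pinprick are simulated).
#' @param eeg_mode `"continuous"` (full filter + epoching chain) or
#'   `"epoched"` (epoch-wise generation, no continuous filtering).
#' @param n_stimuli,isi_range acquisition train parameters.
#' @param stimulated_side arm stimulated, fixes the contralateral montage.
#' @param ... cohort parameters passed to [simulate_cohort()].
#' @return object of class `noxep_config`.
#' @export
study_config <- function(n_subjects = 20, seed = 1,
                         dropout_subjects = integer(0),
                         calibrations = list(chep = default_calibration("chep"),
                                             lep = default_calibration("lep")),
                         snr_gate_db = 3, presence_multiplier = sqrt(2),
                         rejection_uv = 150,
                         family_alpha = 0.05, m_comparisons = 7,
                         capsaicin_thermal_effect = 0,
                         capsaicin_ep_scale = 1,
                         simulate_eeg = TRUE,
                         eeg_mode = c("continuous", "epoched"),
                         n_stimuli = 20, isi_range = c(8, 12),
                         stimulated_side = "left", ...) {
  eeg_mode <- match.arg(eeg_mode)
  stopifnot(n_subjects >= 2, snr_gate_db > 0, presence_multiplier > 0,
            rejection_uv > 0)
  structure(
    list(n_subjects = n_subjects, seed = seed,
         dropout_subjects = as.integer(dropout_subjects),
         calibrations = calibrations,
         snr_gate_db = snr_gate_db,
         presence_multiplier = presence_multiplier,
         rejection_uv = rejection_uv,
         family_alpha = family_alpha, m_comparisons = m_comparisons,
         capsaicin_thermal_effect = capsaicin_thermal_effect,
         capsaicin_ep_scale = capsaicin_ep_scale,
         simulate_eeg = simulate_eeg, eeg_mode = eeg_mode,
         n_stimuli = n_stimuli, isi_range = isi_range,
         stimulated_side = stimulated_side,
         cohort_args = list(...)),
    class = "noxep_config")
}

# Apply the capsaicin amplitude scaling to a ground truth.
scale_truth <- function(truth, scale) {
  if (scale == 1) return(truth)
  for (nm in names(truth$components))
    truth$components[[nm]]$amplitude_uv <-
      truth$components[[nm]]$amplitude_uv * scale
  truth
}

#' Run the four-arm study end-to-end
#'
#' For every recruited subject: familiarization (11 contact-heat stimuli,
#' first discarded) defines the matching target; the double random
#' staircase matches the laser energy; then each of the four arms runs its
#' pinprick pre/post blocks, its 20-stimulus rating series, and (when
#' enabled) a synthetic EEG session pushed through the preprocessing and
#' extraction chain. The comparison reports are assembled from the
#' resulting session table. Deterministic under the configuration seed.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, the session, matching and
#'   pinprick tables, the reports and a run manifest are written there as
#'   CSV/JSON.
#' @return object of class `noxep_study`: `$matching`, `$sessions`,
#'   `$pinprick`, `$reports`, `$manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "noxep_config"))
  observers <- do.call(simulate_cohort,
                       c(list(n_subjects = config$n_subjects,
                              seed = config$seed), config$cohort_args))
  analyzed <- setdiff(seq_len(config$n_subjects), config$dropout_subjects)
  arms <- expand.grid(modality = c("chep", "lep"),
                      condition = c("sham", "capsaicin"),
                      stringsAsFactors = FALSE)
  matching_rows <- list(); session_rows <- list(); pinprick_rows <- list()

  for (i in analyzed) {
    obs <- observers[[i]]
    sseed <- child_seed(config$seed, i)
    fam <- simulate_heat_session(obs, familiarization_train(),
                                 seed = child_seed(sseed, 1))
    target <- familiarization_target(fam)
    match <- run_matching(obs, target, seed = child_seed(sseed, 2))
    matching_rows[[length(matching_rows) + 1]] <- data.frame(
      subject = obs$subject_id,
      target_nrs = target$target_nrs,
      matched_energy = match$result$matched_energy,
      correction_applied = match$result$correction_applied,
      diverged = match$result$diverged)

    # one per-subject ground truth per modality, shared across conditions
    truths <- list(
      chep = sample_ground_truth(config$calibrations$chep,
                                 seed = child_seed(sseed, 3)),
      lep = sample_ground_truth(config$calibrations$lep,
                                seed = child_seed(sseed, 4)))

    for (a in seq_len(nrow(arms))) {
      modality <- arms$modality[a]; condition <- arms$condition[a]
      aseed <- child_seed(sseed, 10 + a)
      shift <- if (condition == "capsaicin")
        config$capsaicin_thermal_effect else 0
      maybe_seed(child_seed(aseed, 1))
      ratings <- if (modality == "chep") {
        shifted <- obs
        shifted$heat_mean_nrs <- clip(obs$heat_mean_nrs + shift, 0, 10)
        simulate_heat_session(shifted,
                              stimulus_train("contact_heat",
                                             config$n_stimuli,
                                             config$isi_range))
      } else {
        e <- match$result$matched_energy
        nrs_round(obs$slope * pmax(0, e - obs$pain_threshold_energy) +
                    shift +
                    stats::rnorm(config$n_stimuli, 0, obs$rating_noise_sd))
      }
      pp <- simulate_pinprick_pair(condition, modality,
                                   seed = child_seed(aseed, 2))
      pinprick_rows[[length(pinprick_rows) + 1]] <- data.frame(
        subject = obs$subject_id, session = modality,
        condition = condition,
        pre_mean = as.numeric(block_mean(pp$pre)),
        post_mean = as.numeric(block_mean(pp$post)),
        delta = hyperalgesia_delta(pp$pre, pp$post))

      row <- data.frame(subject = obs$subject_id, modality = modality,
                        condition = condition,
                        mean_nrs = session_thermal_mean(ratings,
                                                        config$n_stimuli))
      if (config$simulate_eeg) {
        truth <- truths[[modality]]
        if (condition == "capsaicin")
          truth <- scale_truth(truth, config$capsaicin_ep_scale)
        train <- stimulus_train(
          if (modality == "chep") "contact_heat" else "laser",
          config$n_stimuli, config$isi_range)
        cont <- config$eeg_mode == "continuous"
        ses <- synthesize_session(truth, train, continuous = cont,
                                  seed = child_seed(aseed, 3))
        ep <- if (cont) {
          extract_recording(ses, modality, config$stimulated_side,
                            snr_gate_db = config$snr_gate_db,
                            rejection_uv = config$rejection_uv,
                            presence_multiplier = config$presence_multiplier)
        } else {
          extract_session(ses, modality, config$stimulated_side,
                          snr_gate_db = config$snr_gate_db,
                          rejection_uv = config$rejection_uv,
                          presence_multiplier = config$presence_multiplier)
        }
        epdf <- as.data.frame(ep)
        row <- cbind(row, excluded = epdf$excluded, snr_db = epdf$snr_db,
                     n1_latency = epdf$n1_latency,
                     n1_amplitude = epdf$n1_amplitude,
                     n2_latency = epdf$n2_latency,
                     n2_amplitude = epdf$n2_amplitude,
                     p2_latency = epdf$p2_latency,
                     p2_amplitude = epdf$p2_amplitude,
                     n2p2_amplitude = epdf$n2p2_amplitude)
      } else {
        row <- cbind(row, excluded = FALSE, snr_db = NA_real_,
                     n1_latency = NA_real_, n1_amplitude = NA_real_,
                     n2_latency = NA_real_, n2_amplitude = NA_real_,
                     p2_latency = NA_real_, p2_amplitude = NA_real_,
                     n2p2_amplitude = NA_real_)
      }
      session_rows[[length(session_rows) + 1]] <- row
    }
  }

  matching <- do.call(rbind, matching_rows)
  sessions <- do.call(rbind, session_rows)
  pinprick <- do.call(rbind, pinprick_rows)
  reports <- if (config$simulate_eeg) {
    build_reports(sessions, pinprick, config$family_alpha,
                  config$m_comparisons)
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("noxep")),
    seed = config$seed,
    n_recruited = config$n_subjects,
    n_analyzed = length(analyzed),
    dropout_subjects = config$dropout_subjects,
    arms = paste(arms$modality, arms$condition, sep = "/"),
    eeg_mode = config$eeg_mode,
    thresholds = list(snr_gate_db = config$snr_gate_db,
                      presence_multiplier = config$presence_multiplier,
                      rejection_uv = config$rejection_uv),
    family = list(alpha = config$family_alpha, m = config$m_comparisons,
                  adjusted_alpha = bonferroni_adjust(config$family_alpha,
                                                     config$m_comparisons)),
    decisions = list(
      filter = "1-40 Hz Hamming FIR, 1 Hz low transition, zero-phase, applied before epoching",
      baseline_window = "full pre-stimulus second [-1, 0) s",
      tie_rule = "staircase holds energy when rating equals a nonzero target",
      staircase = "both staircases always run 10 trials; medians over all 10",
      median_even = "median of an even count = mean of the central pair (0.125 J grid)",
      energy_cap = "5 J, clamping reported",
      snr_convention = "20*log10 of the voltage RMS ratio",
      snr_pre_window = "full second for the session gate, 500 ms for presence",
      presence_rule = "|peak| >= sqrt(2) x RMS(500 ms pre-trigger)",
      n2_onset = "last half-amplitude crossing before the N2 peak",
      absent_components = "amplitude 0 uV, latency missing",
      session_order = "arm order randomized per subject, no modelled carry-over"))

  study <- structure(list(config = config, matching = matching,
                          sessions = sessions, pinprick = pinprick,
                          reports = reports, manifest = manifest),
                     class = "noxep_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

# Write the study bundle as CSV tables plus a JSON manifest.
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$matching, file.path(out_dir, "matching.csv"),
                   row.names = FALSE)
  utils::write.csv(study$sessions, file.path(out_dir, "sessions.csv"),
                   row.names = FALSE)
  utils::write.csv(study$pinprick, file.path(out_dir, "pinprick.csv"),
                   row.names = FALSE)
  if (!is.null(study$reports)) {
    for (nm in c("baseline", "condition_chep", "condition_lep", "thermal",
                 "mechanical", "matching")) {
      tab <- study$reports[[nm]]
      if (!is.null(tab))
        utils::write.csv(tab,
                         file.path(out_dir, sprintf("report_%s.csv", nm)),
                         row.names = FALSE)
    }
  }
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.noxep_study <- function(x, ...) {
  cat(sprintf("<study> %d subjects analyzed (%d recruited), seed %d\n",
              x$manifest$n_analyzed, x$manifest$n_recruited,
              x$config$seed))
  if (!is.null(x$reports)) print(x$reports)
  invisible(x)
}
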