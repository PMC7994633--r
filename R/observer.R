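#' Synthetic psychophysical observer
#'
#' An observer maps stimulus energy (laser, joules) to a 0-10 numeric rating
#' scale (NRS) rating through a piecewise-linear psychometric model with
#' additive Gaussian report noise, and rates contact-heat stimuli from a
#' session-level normal distribution. Ratings are integer NRS values: the
#' latent response is rounded and clipped to [0, 10], mirroring how subjects
#' report on the scale (0 no pain, 1 first burning/stinging sensation,
#' 10 worst imaginable).
#'
#' @param subject_id character label for the simulated subject.
#' @param pain_threshold_energy laser pain threshold in joules (> 0); below
#'   it the latent drive is zero.
#' @param slope psychometric slope in NRS units per joule above threshold
#'   (> 0).
#' @param rating_noise_sd standard deviation of the additive report noise,
#'   NRS units (>= 0).
#' @param heat_mean_nrs mean of the observer's contact-heat rating
#'   distribution, NRS units.
#' @param heat_sd_nrs standard deviation of the contact-heat rating
#'   distribution, NRS units (>= 0).
#' @param seed optional integer seed stored with the observer.
#' @return An object of class `noxep_observer`.
#' @examples
#' obs <- observer("S01")
#' simulate_rating(obs, energy = 3.0, seed = 1)
#' @export
observer <- function(subject_id = "S01",
                     pain_threshold_energy = 1.0,
                     slope = 2.5,
                     rating_noise_sd = 0.5,
                     heat_mean_nrs = 3.0,
                     heat_sd_nrs = 1.6,
                     seed = NULL) {
  stopifnot(pain_threshold_energy > 0, slope > 0, rating_noise_sd >= 0,
            heat_sd_nrs >= 0, heat_mean_nrs >= 0, heat_mean_nrs <= 10)
  structure(
    list(subject_id = as.character(subject_id),
         pain_threshold_energy = pain_threshold_energy,
         slope = slope,
         rating_noise_sd = rating_noise_sd,
         heat_mean_nrs = heat_mean_nrs,
         heat_sd_nrs = heat_sd_nrs,
         seed = seed),
    class = "noxep_observer")
}

#' @export
print.noxep_observer <- function(x, ...) {
  cat(sprintf(
    "<observer %s> threshold %.2f J, slope %.2f NRS/J, noise sd %.2f; heat %.1f +/- %.1f NRS\n",
    x$subject_id, x$pain_threshold_energy, x$slope, x$rating_noise_sd,
    x$heat_mean_nrs, x$heat_sd_nrs))
  invisible(x)
}

#' Simulate a single laser rating
#'
#' Returns `clip(round(slope * max(0, energy - threshold) + eps), 0, 10)` with
#' `eps ~ Normal(0, rating_noise_sd)`. Vectorised over `energy`; each element
#' draws its own noise term.
#'
#' @param obs a [observer()].
#' @param energy stimulus energy in joules (>= 0).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return integer NRS rating(s) in \[0, 10\].
#' @export
simulate_rating <- function(obs, energy, seed = NULL) {
  stopifnot(inherits(obs, "noxep_observer"))
  if (any(energy < 0)) stop("invalid stimulus: energy must be >= 0")
  maybe_seed(seed)
  drive <- obs$slope * pmax(0, energy - obs$pain_threshold_energy)
  eps <- stats::rnorm(length(energy), 0, obs$rating_noise_sd)
  nrs_round(drive + eps)
}

#' Simulate a contact-heat stimulation session
#'
#' Draws one NRS rating per stimulus from the observer's contact-heat
#' distribution: `round(clip(Normal(heat_mean_nrs, heat_sd_nrs), 0, 10))`.
#' The default observer calibration (3.0 +/- 1.6 NRS) reproduces the sham
#' contact-heat pain distribution used throughout the package.
#'
#' @param obs a [observer()].
#' @param train a [stimulus_train()] with `modality = "contact_heat"`.
#' @param seed optional seed; defaults to the train's seed if set.
#' @return integer vector of `train$n_stimuli` NRS ratings.
#' @export
simulate_heat_session <- function(obs, train, seed = NULL) {
  stopifnot(inherits(obs, "noxep_observer"), inherits(train, "noxep_train"))
  if (train$modality != "contact_heat")
    stop("simulate_heat_session requires a contact_heat train")
  maybe_seed(seed %||% train$seed)
  latent <- stats::rnorm(train$n_stimuli, obs$heat_mean_nrs, obs$heat_sd_nrs)
  as.integer(round(clip(latent, 0, 10)))
}

#' Stimulus train parameters
#'
#' Describes one acquisition or familiarization run: 20 stimuli per
#' acquisition session (11 for familiarization), inter-stimulus interval
#' uniform in 8-12 s. Thermode ramp parameters (35 degC baseline, 52 degC
#' peak, 70 degC/s heating, 40 degC/s cooling) and the 5 ms / 5 mm laser
#' pulse are carried as metadata only; they do not enter the simulation.
#'
#' @param modality `"contact_heat"` or `"laser"`.
#' @param n_stimuli number of stimuli (default 20; use 11 for
#'   familiarization).
#' @param isi_range inter-stimulus interval range in seconds.
#' @param energy laser energy in joules (laser trains).
#' @param peak_temperature,baseline_temperature,heating_rate,cooling_rate,pulse_ms
#'   stimulator metadata.
#' @param seed optional integer seed stored with the train.
#' @return An object of class `noxep_train`.
#' @export
stimulus_train <- function(modality = c("contact_heat", "laser"),
                           n_stimuli = 20,
                           isi_range = c(8, 12),
                           energy = NULL,
                           peak_temperature = 52,
                           baseline_temperature = 35,
                           heating_rate = 70,
                           cooling_rate = 40,
                           pulse_ms = 5,
                           seed = NULL) {
  modality <- match.arg(modality)
  stopifnot(n_stimuli >= 1, length(isi_range) == 2,
            isi_range[1] > 0, isi_range[1] <= isi_range[2])
  structure(
    list(modality = modality, n_stimuli = as.integer(n_stimuli),
         isi_range = isi_range, energy = energy,
         peak_temperature = peak_temperature,
         baseline_temperature = baseline_temperature,
         heating_rate = heating_rate, cooling_rate = cooling_rate,
         pulse_ms = pulse_ms, seed = seed),
    class = "noxep_train")
}

#' Familiarization train (11 contact-heat stimuli)
#'
#' @param ... passed to [stimulus_train()].
#' @export
familiarization_train <- function(...) {
  stimulus_train(modality = "contact_heat", n_stimuli = 11, ...)
}

#' Simulate a cohort of observers
#'
#' Between-subject heterogeneity is carried by the contact-heat mean: each
#' subject's `heat_mean_nrs` is drawn from a normal distribution with the
#' cohort mean and between-subject SD (defaults 3.0 and 1.6 NRS, the sham
#' contact-heat pain distribution), truncated to \[0, 10\]. The psychometric
#' threshold and slope default to the cohort values with optional
#' heterogeneity SDs.
#'
#' @param n_subjects number of observers.
#' @param seed integer seed driving all draws.
#' @param heat_mean_pop,heat_sd_between cohort mean and between-subject SD of
#'   the contact-heat session mean, NRS.
#' @param heat_sd_within within-session contact-heat rating SD, NRS.
#' @param threshold,threshold_sd,slope,slope_sd psychometric parameters and
#'   optional between-subject SDs (defaults 0: homogeneous cohort).
#' @param rating_noise_sd laser report noise SD, NRS.
#' @return list of [observer()] objects.
#' @export
simulate_cohort <- function(n_subjects = 20, seed = 1,
                            heat_mean_pop = 3.0, heat_sd_between = 1.6,
                            heat_sd_within = 1.0,
                            threshold = 1.0, threshold_sd = 0,
                            slope = 2.5, slope_sd = 0,
                            rating_noise_sd = 0.5) {
  maybe_seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    hm <- clip(stats::rnorm(1, heat_mean_pop, heat_sd_between), 0, 10)
    th <- max(0.25, stats::rnorm(1, threshold, threshold_sd))
    sl <- max(0.25, stats::rnorm(1, slope, slope_sd))
    observer(subject_id = sprintf("S%02d", i),
             pain_threshold_energy = th, slope = sl,
             rating_noise_sd = rating_noise_sd,
             heat_mean_nrs = hm, heat_sd_nrs = heat_sd_within,
             seed = child_seed(seed, i))
  })
}
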