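#' Matching target from familiarization ratings
#'
#' The perceptual target for laser intensity matching is the mean of the
#' contact-heat familiarization ratings after discarding the first stimulus
#' (novelty/surprise): 11 ratings in, the mean of the last 10 out.
#'
#' @param ratings integer NRS ratings of length 11.
#' @return object of class `noxep_target` with `target_nrs`.
#' @examples
#' familiarization_target(c(9, rep(3, 10)))$target_nrs  # 3
#' @export
familiarization_target <- function(ratings) {
  if (length(ratings) != 11)
    stop("familiarization requires exactly 11 ratings")
  stopifnot(all(ratings >= 0 & ratings <= 10))
  matching_target(mean(ratings[-1]))
}

#' @rdname familiarization_target
#' @param target_nrs a target on the NRS scale in \[0, 10\].
#' @export
matching_target <- function(target_nrs) {
  stopifnot(target_nrs >= 0, target_nrs <= 10)
  structure(list(target_nrs = target_nrs, n_familiarization = 11L,
                 n_used = 10L),
            class = "noxep_target")
}

#' Double-random-staircase energy update rule
#'
#' One step of the staircase: no pain reported (rating 0) increments by the
#' large step (0.5 J); pain below the target increments and pain above the
#' target decrements by the small step (0.25 J). A rating exactly at a
#' (nonzero) target holds the current energy by default (`tie = "hold"`);
#' `tie = "down"` treats it as above-target. The result is clamped to
#' \[`step_small`, `energy_cap`\] with a message, never silently.
#'
#' @param current current energy, joules (> 0).
#' @param rating NRS rating of the current stimulus.
#' @param target target NRS value.
#' @param step_large,step_small staircase steps, joules.
#' @param energy_cap maximum deliverable energy, joules.
#' @param tie behaviour when `rating == target`.
#' @return next stimulus energy, joules.
#' @export
next_energy <- function(current, rating, target,
                        step_large = 0.5, step_small = 0.25,
                        energy_cap = 5, tie = c("hold", "down")) {
  tie <- match.arg(tie)
  stopifnot(current > 0, rating >= 0, rating <= 10)
  nxt <- if (rating == 0) {
    current + step_large
  } else if (rating < target) {
    current + step_small
  } else if (rating > target || tie == "down") {
    current - step_small
  } else {
    current
  }
  if (nxt > energy_cap) {
    message(sprintf("staircase clamped at energy cap %.2f J", energy_cap))
    nxt <- energy_cap
  }
  if (nxt < step_small) {
    message(sprintf("staircase clamped at floor %.2f J", step_small))
    nxt <- step_small
  }
  nxt
}

# Interleaving order for the two staircases: a seeded random permutation of
# n_trials A's and B's, rejection-sampled so neither staircase occupies more
# than `max_consecutive` consecutive trials.
interleave_order <- function(n_trials, max_consecutive = 3, max_tries = 1000) {
  base <- rep(c("A", "B"), each = n_trials)
  for (i in seq_len(max_tries)) {
    ord <- sample(base)
    runs <- rle(ord)$lengths
    if (max(runs) <= max_consecutive) return(ord)
  }
  stop("failed to draw an interleaving order")  # unreachable in practice
}

#' Run the double random staircase (DRS) matching procedure
#'
#' Two concurrent staircases, randomly interspersed (no more than 3
#' consecutive trials from the same staircase), each delivering 10 stimuli
#' starting at 1.5 J and updated by [next_energy()]. Both staircases always
#' run their full 10 trials; a staircase that never reverses direction is
#' flagged as non-converged rather than extended. On completion each
#' staircase's median energy and median rating are computed over its own 10
#' trials (median of an even count is the mean of the two central values, so
#' the matched energy lives on a 0.125 J grid). The matched energy is the
#' mean of the two median energies, incremented by 0.25 J when the mean of
#' the two median ratings falls short of the target (subjects tend to
#' underestimate laser intensity).
#'
#' @param rate_fn either a [observer()] or a function `function(energy)`
#'   returning an NRS rating.
#' @param target a [matching_target()] / [familiarization_target()] or a
#'   bare numeric target.
#' @param seed integer seed for the interleaving order and any observer
#'   noise.
#' @param n_trials trials per staircase.
#' @param start_energy starting energy, joules.
#' @param step_large,step_small,energy_cap,tie passed to [next_energy()].
#' @param max_consecutive interleaving constraint.
#' @return object of class `noxep_match`: `$trials` (trial, staircase,
#'   energy, rating), `$result` with per-staircase medians, the matched
#'   energy, and flags (`correction_applied`, `diverged`, `nonconverged`).
#' @export
run_matching <- function(rate_fn, target, seed = 1,
                         n_trials = 10, start_energy = 1.5,
                         step_large = 0.5, step_small = 0.25,
                         energy_cap = 5, tie = "hold",
                         max_consecutive = 3) {
  if (inherits(target, "noxep_target")) target <- target$target_nrs
  stopifnot(target >= 0, target <= 10)
  if (inherits(rate_fn, "noxep_observer")) {
    obs <- rate_fn
    rate_fn <- function(energy) simulate_rating(obs, energy)
  }
  stopifnot(is.function(rate_fn))
  # scripted oracles may take (energy, staircase) to key ratings per track
  pass_staircase <- length(formals(rate_fn)) >= 2
  maybe_seed(seed)
  ord <- interleave_order(n_trials, max_consecutive)
  energy <- c(A = start_energy, B = start_energy)
  trials <- data.frame(trial = seq_along(ord), staircase = ord,
                       energy = NA_real_, rating = NA_real_)
  for (i in seq_along(ord)) {
    sc <- ord[i]
    e <- energy[[sc]]
    r <- tryCatch(if (pass_staircase) rate_fn(e, sc) else rate_fn(e),
                  error = function(err) {
      stop(structure(
        class = c("noxep_matching_error", "error", "condition"),
        list(message = sprintf(
               "rating callback failed at trial %d (%s): %s",
               i, sc, conditionMessage(err)),
             call = sys.call(-4), trajectory = trials[seq_len(i - 1), ])))
    })
    if (length(r) != 1 || is.na(r) || r < 0 || r > 10)
      stop("rating callback must return a single NRS value in [0, 10]")
    trials$energy[i] <- e
    trials$rating[i] <- r
    energy[[sc]] <- next_energy(e, r, target, step_large, step_small,
                                energy_cap, tie)
  }
  per <- lapply(c(A = "A", B = "B"), function(sc) {
    tr <- trials[trials$staircase == sc, ]
    list(median_energy = stats::median(tr$energy),
         median_nrs = stats::median(tr$rating),
         reversals = n_reversals(tr$energy))
  })
  matched <- mean(c(per$A$median_energy, per$B$median_energy))
  correction <- mean(c(per$A$median_nrs, per$B$median_nrs)) < target
  if (correction) matched <- matched + step_small
  diverged <- abs(per$A$median_energy - per$B$median_energy) > 1
  if (diverged)
    warning("staircase medians diverge by more than 1 J; averaging anyway")
  structure(
    list(trials = trials,
         target_nrs = target,
         result = list(
           median_energy_A = per$A$median_energy,
           median_energy_B = per$B$median_energy,
           median_nrs_A = per$A$median_nrs,
           median_nrs_B = per$B$median_nrs,
           matched_energy = matched,
           correction_applied = correction,
           diverged = diverged,
           nonconverged = c(A = per$A$reversals == 0,
                            B = per$B$reversals == 0))),
    class = "noxep_match")
}

# Number of direction reversals in an energy trajectory.
n_reversals <- function(energy) {
  d <- diff(energy)
  d <- d[d != 0]
  if (length(d) < 2) return(0L)
  sum(diff(sign(d)) != 0)
}

#' @export
print.noxep_match <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<DRS match> target %.2f NRS; medians A %.3f J / B %.3f J; matched %.3f J%s\n",
    x$target_nrs, r$median_energy_A, r$median_energy_B, r$matched_energy,
    if (r$correction_applied) " (+0.25 J correction)" else ""))
  invisible(x)
}
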