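#' Pinprick rating block
#'
#' One block of the mechanical pain-sensitivity protocol: seven weighted
#' pinpricks (8, 16, 32, 64, 128, 256, 512 mN), each applied five times in
#' randomized order, rated on the 0-10 NRS. Exactly 35 ratings per block.
#'
#' @param ratings data frame with columns `force_mN`, `rep`, `nrs`.
#' @param phase `"pre"` or `"post"` (cream application).
#' @param condition `"sham"` or `"capsaicin"`.
#' @param session `"chep"` or `"lep"` (which stimulation session the block
#'   belongs to).
#' @return object of class `noxep_pinprick`.
#' @export
pinprick_block <- function(ratings, phase = c("pre", "post"),
                           condition = c("sham", "capsaicin"),
                           session = c("chep", "lep")) {
  phase <- match.arg(phase)
  condition <- match.arg(condition)
  session <- match.arg(session)
  stopifnot(is.data.frame(ratings),
            all(c("force_mN", "rep", "nrs") %in% names(ratings)))
  if (nrow(ratings) != 35)
    stop("a pinprick block holds exactly 35 ratings (7 forces x 5 reps)")
  counts <- table(ratings$force_mN)
  if (!setequal(names(counts), pinprick_forces()) || any(counts != 5))
    stop("each of the forces 8,16,32,64,128,256,512 mN must appear 5 times")
  stopifnot(all(ratings$nrs >= 0 & ratings$nrs <= 10))
  structure(list(ratings = ratings, phase = phase, condition = condition,
                 session = session),
            class = "noxep_pinprick")
}

#' @rdname pinprick_block
#' @export
pinprick_forces <- function() c(8, 16, 32, 64, 128, 256, 512)

#' Overall mean of a pinprick block
#'
#' The per-block sensitivity measure: the arithmetic mean of all 35
#' ratings. Per-force means are available via `attr(, "per_force")` as a
#' diagnostic only; the analysis collapses over forces.
#'
#' @param block a [pinprick_block()].
#' @return mean NRS, with a per-force breakdown attached as an attribute.
#' @export
block_mean <- function(block) {
  stopifnot(inherits(block, "noxep_pinprick"))
  m <- mean(block$ratings$nrs)
  attr(m, "per_force") <- tapply(block$ratings$nrs, block$ratings$force_mN,
                                 mean)
  m
}

#' Secondary-hyperalgesia delta
#'
#' Change in overall pinprick sensitivity after cream application:
#' `block_mean(post) - block_mean(pre)`. Both blocks must belong to the
#' same condition and session.
#'
#' @param pre,post [pinprick_block()]s from the same session/condition.
#' @return NRS difference (positive = increased sensitivity).
#' @export
hyperalgesia_delta <- function(pre, post) {
  stopifnot(inherits(pre, "noxep_pinprick"), inherits(post, "noxep_pinprick"))
  if (pre$condition != post$condition || pre$session != post$session)
    stop("pre and post blocks must come from the same condition and session")
  if (pre$phase != "pre" || post$phase != "post")
    stop("arguments must be the pre- and post-cream blocks, in that order")
  as.numeric(block_mean(post)) - as.numeric(block_mean(pre))
}

#' Session mean thermal rating
#'
#' Mean NRS over the 20 per-stimulus ratings of an acquisition session.
#' A different count triggers a warning and the mean over the available
#' ratings.
#'
#' @param ratings numeric NRS ratings.
#' @param expected expected number of ratings.
#' @return mean NRS.
#' @export
session_thermal_mean <- function(ratings, expected = 20) {
  stopifnot(all(ratings >= 0 & ratings <= 10))
  if (length(ratings) != expected)
    warning(sprintf("expected %d ratings, got %d; averaging available ones",
                    expected, length(ratings)))
  mean(ratings)
}

# Table of per-condition/session cream effects on the pinprick block mean
# (NRS): sham deltas centre near zero, capsaicin deltas are positive
# (secondary mechanical hyperalgesia).
pinprick_effect_defaults <- function() {
  data.frame(session = c("chep", "chep", "lep", "lep"),
             condition = c("sham", "capsaicin", "sham", "capsaicin"),
             delta_mean = c(-0.1, 0.1, 0.0, 0.2),
             delta_sd = c(0.2, 0.2, 0.3, 0.4))
}

#' Simulate a pre/post pair of pinprick blocks
#'
#' Baseline per-force ratings follow a log2-force psychometric rule
#' (`0.3 + 0.45 * log2(force / 8)` NRS plus report noise, rounded to the
#' integer scale), spanning roughly 0 NRS at 8 mN to 3 NRS at 512 mN. The
#' post-cream block shifts the latent ratings by a subject-level effect
#' drawn from the per-condition/session calibration
#' (`pinprick_effect_defaults()`).
#'
#' @param condition `"sham"` or `"capsaicin"`.
#' @param session `"chep"` or `"lep"`.
#' @param seed integer seed.
#' @param noise_sd report noise SD, NRS.
#' @param effects calibration table (see [pinprick_effect_defaults()]).
#' @return list with `pre` and `post` [pinprick_block()]s and the drawn
#'   `true_effect`.
#' @export
simulate_pinprick_pair <- function(condition = c("sham", "capsaicin"),
                                   session = c("chep", "lep"),
                                   seed = NULL, noise_sd = 0.5,
                                   effects = pinprick_effect_defaults()) {
  condition <- match.arg(condition)
  session <- match.arg(session)
  maybe_seed(seed)
  eff <- effects[effects$session == session & effects$condition == condition, ]
  stopifnot(nrow(eff) == 1)
  true_effect <- stats::rnorm(1, eff$delta_mean, eff$delta_sd)
  one_block <- function(phase, shift) {
    forces <- sample(rep(pinprick_forces(), each = 5))   # randomized order
    latent <- 0.3 + 0.45 * log2(forces / 8) + shift +
      stats::rnorm(length(forces), 0, noise_sd)
    df <- data.frame(force_mN = forces,
                     rep = stats::ave(forces, forces, FUN = seq_along),
                     nrs = nrs_round(latent))
    pinprick_block(df, phase = phase, condition = condition,
                   session = session)
  }
  list(pre = one_block("pre", 0), post = one_block("post", true_effect),
       true_effect = true_effect)
}
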