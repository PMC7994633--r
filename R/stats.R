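#' Paired t-test with pairwise deletion
#'
#' Two-sided paired t-test on the complete pairs of `x` and `y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' Incomplete pairs (missing in either arm) are dropped.
#'
#' @param x,y paired measurements, same units.
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    # identical pairs are a well-defined null (t = 0); a constant nonzero
    # difference has no estimable variance and is refused
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    stop("degenerate sample: zero variance of the paired differences")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), n = n)
}

#' Pearson product-moment correlation
#'
#' @param x,y paired measurements (at least 3 complete pairs, nonzero
#'   variances).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate sample: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Intraclass correlation, two-way average agreement
#'
#' McGraw & Wong ICC(A,k): two-way random effects, absolute agreement,
#' average of k measurements, computed from the two-way ANOVA mean squares
#' as `(MSR - MSE) / (MSR + (MSC - MSE) / n)` where MSR, MSC and MSE are
#' the row (subject), column (method) and residual mean squares. The
#' consistency variant ICC(C,k) = `(MSR - MSE) / MSR` is available for
#' sensitivity analysis.
#'
#' @param mat numeric matrix, subjects x methods (no missing cells, at
#'   least 5 subjects).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return list with `icc`, the mean squares, and `degenerate` (TRUE when
#'   the agreement denominator is not positive; the value is still
#'   returned).
#' @export
icc_a_k <- function(mat, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  if (any(is.na(mat))) stop("no missing cells allowed")
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 5, k >= 2)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- FALSE
  if (type == "agreement") {
    denom <- msr + (msc - mse) / n
    if (denom <= 0) degenerate <- TRUE
    icc <- (msr - mse) / denom
  } else {
    icc <- (msr - mse) / msr
  }
  list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k,
       type = type, degenerate = degenerate)
}

#' Bonferroni-adjusted significance level
#'
#' `alpha / m`. With the seven evoked-potential outcomes (N1/N2/P2 latency
#' and amplitude plus N2P2) at family alpha 0.05 this is 0.00714..,
#' reported to three decimals as 0.007.
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return adjusted level.
#' @export
bonferroni_adjust <- function(alpha = 0.05, m = 7) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

# p-value display convention: three decimals, "< 0.001" below that.
format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
}

ep_outcomes <- function() {
  c("n1_latency", "n1_amplitude", "n2_latency", "n2_amplitude",
    "p2_latency", "p2_amplitude", "n2p2_amplitude")
}

# Paired comparison of one outcome between two arms of a session table.
# Rows of excluded sessions must already carry NA outcomes. Returns a
# one-row data frame; not-computable outcomes carry NA statistics.
compare_outcome <- function(a, b, outcome, adjusted_alpha) {
  res <- tryCatch(paired_t(a, b), error = function(e) NULL)
  keep <- stats::complete.cases(a, b)
  if (is.null(res)) {
    return(data.frame(outcome = outcome,
                      mean_a = NA_real_, sd_a = NA_real_,
                      mean_b = NA_real_, sd_b = NA_real_,
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      p_formatted = NA_character_, significant = NA))
  }
  data.frame(outcome = outcome,
             mean_a = mean(a[keep]), sd_a = stats::sd(a[keep]),
             mean_b = mean(b[keep]), sd_b = stats::sd(b[keep]),
             t = res$t, df = res$df, p = res$p,
             p_formatted = format_p(res$p),
             significant = res$p < adjusted_alpha)
}

#' Assemble the study's comparison reports
#'
#' Builds the session-level statistical layer from a table of per-session
#' extraction results and ratings: the baseline contact-heat vs laser
#' comparison (seven outcomes, Bonferroni family), the sham vs capsaicin
#' comparison per modality (same family), the perceived-pain matching
#' report (Pearson r and ICC(A,2) between contact-heat and laser session
#' mean NRS in the sham condition), the thermal sham vs capsaicin
#' comparison per modality, and, when a pinprick table is supplied, the
#' mechanical hyperalgesia comparison per session type.
#'
#' Missing-data policy: sessions excluded by the SNR gate contribute no
#' outcomes (their rows are NA); absent components enter amplitude
#' comparisons as 0 uV but latency comparisons as missing, so degrees of
#' freedom vary by outcome.
#'
#' @param sessions data frame with columns `subject`, `modality`
#'   (`"chep"`/`"lep"`), `condition` (`"sham"`/`"capsaicin"`), `excluded`,
#'   the seven outcome columns (`n1_latency`, ..., `n2p2_amplitude`) and
#'   `mean_nrs`.
#' @param pinprick optional data frame with `subject`, `session`,
#'   `condition`, `delta`.
#' @param family_alpha family-wise level.
#' @param m_comparisons size of the evoked-potential comparison family.
#' @return object of class `noxep_reports` (a list of data frames plus the
#'   adjusted alpha).
#' @export
build_reports <- function(sessions, pinprick = NULL,
                          family_alpha = 0.05, m_comparisons = 7) {
  need <- c("subject", "modality", "condition", "excluded", ep_outcomes(),
            "mean_nrs")
  missing <- setdiff(need, names(sessions))
  if (length(missing) > 0)
    stop(sprintf("sessions table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  adj <- bonferroni_adjust(family_alpha, m_comparisons)
  sessions[sessions$excluded %in% TRUE, c(ep_outcomes(), "mean_nrs")] <- NA

  arm <- function(modality, condition) {
    s <- sessions[sessions$modality == modality &
                    sessions$condition == condition, ]
    s[match(sort(unique(sessions$subject)), s$subject), ]
  }
  compare_arms <- function(a, b) {
    do.call(rbind, lapply(ep_outcomes(), function(oc)
      compare_outcome(a[[oc]], b[[oc]], oc, adj)))
  }

  chep_sham <- arm("chep", "sham"); lep_sham <- arm("lep", "sham")
  chep_caps <- arm("chep", "capsaicin"); lep_caps <- arm("lep", "capsaicin")

  baseline <- compare_arms(chep_sham, lep_sham)

  condition_chep <- compare_arms(chep_sham, chep_caps)
  condition_lep <- compare_arms(lep_sham, lep_caps)

  matching <- tryCatch({
    r <- pearson_r(chep_sham$mean_nrs, lep_sham$mean_nrs)
    keep <- stats::complete.cases(chep_sham$mean_nrs, lep_sham$mean_nrs)
    icc <- icc_a_k(cbind(chep_sham$mean_nrs[keep], lep_sham$mean_nrs[keep]))
    data.frame(pearson_r = r$r, pearson_p = r$p, icc_a2 = icc$icc,
               n = r$n)
  }, error = function(e) data.frame(pearson_r = NA_real_,
                                    pearson_p = NA_real_,
                                    icc_a2 = NA_real_, n = NA_integer_))

  thermal <- do.call(rbind, list(
    cbind(measure = "contact_heat_pain",
          compare_outcome(chep_sham$mean_nrs, chep_caps$mean_nrs,
                          "mean_nrs", family_alpha)),
    cbind(measure = "laser_pain",
          compare_outcome(lep_sham$mean_nrs, lep_caps$mean_nrs,
                          "mean_nrs", family_alpha))))

  mechanical <- NULL
  if (!is.null(pinprick)) {
    pp_arm <- function(session, condition) {
      p <- pinprick[pinprick$session == session &
                      pinprick$condition == condition, ]
      p$delta[match(sort(unique(pinprick$subject)), p$subject)]
    }
    mechanical <- do.call(rbind, list(
      cbind(measure = "pinprick_delta_chep_session",
            compare_outcome(pp_arm("chep", "sham"),
                            pp_arm("chep", "capsaicin"),
                            "delta", family_alpha)),
      cbind(measure = "pinprick_delta_lep_session",
            compare_outcome(pp_arm("lep", "sham"),
                            pp_arm("lep", "capsaicin"),
                            "delta", family_alpha))))
  }

  structure(list(baseline = baseline,
                 condition_chep = condition_chep,
                 condition_lep = condition_lep,
                 matching = matching,
                 thermal = thermal,
                 mechanical = mechanical,
                 family_alpha = family_alpha,
                 adjusted_alpha = adj,
                 adjusted_alpha_reported = round(adj, 3)),
            class = "noxep_reports")
}

#' @export
print.noxep_reports <- function(x, ...) {
  cat(sprintf("<comparison reports> family alpha %.2f, adjusted %.3f\n",
              x$family_alpha, x$adjusted_alpha_reported))
  cat("\nBaseline contact heat vs laser (sham):\n")
  print(x$baseline, row.names = FALSE, digits = 3)
  cat("\nPerceived-pain matching (sham sessions):\n")
  print(x$matching, row.names = FALSE, digits = 3)
  invisible(x)
}
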