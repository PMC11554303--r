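#' FACS composite score for one trial
#'
#' The facial outcome is the product of the mean action-unit frequency and
#' the mean action-unit intensity across the four pain-related AU categories
#' (AU4 brow lowering, AU6-7 orbit tightening, AU9-10 levator contraction,
#' AU43 eye closure), with absent AUs counted as 0. The modelled score is the
#' natural-log transform `ln(raw + 1)`, which maps a raw score of 0 to 0 and
#' tames the right skew of the raw composite.
#'
#' @param record A single trial: a one-row data frame (or list) with columns
#'   `AU4_freq, AU4_int, AU67_freq, AU67_int, AU910_freq, AU910_int,
#'   AU43_freq, AU43_int`.
#' @return A list of class `facs_score` with `raw_composite` and
#'   `transformed`.
#' @export
compute_facs_composite <- function(record) {
  freq <- as.numeric(record[c("AU4_freq", "AU67_freq", "AU910_freq", "AU43_freq")])
  int <- as.numeric(record[c("AU4_int", "AU67_int", "AU910_int", "AU43_int")])
  if (anyNA(freq) || anyNA(int))
    stop("record must carry frequency and intensity for all four AU categories",
         call. = FALSE)
  if (any(freq < 0) || any(int < 0))
    stop("AU frequencies and intensities must be non-negative", call. = FALSE)
  raw <- mean(freq) * mean(int)
  structure(list(raw_composite = raw, transformed = log1p(raw)),
            class = "facs_score")
}

#' FACS composite scores for a behavioral table
#'
#' Vectorised version of [compute_facs_composite()].
#'
#' @param records Behavioral data frame (one row per trial) with the eight
#'   AU columns; a `trial_id` column is carried through if present.
#' @return Data frame with `trial_id`, `raw`, `transformed`.
#' @export
facs_scores <- function(records) {
  freq <- as.matrix(records[, c("AU4_freq", "AU67_freq", "AU910_freq", "AU43_freq")])
  int <- as.matrix(records[, c("AU4_int", "AU67_int", "AU910_int", "AU43_int")])
  if (any(freq < 0) || any(int < 0))
    stop("AU frequencies and intensities must be non-negative", call. = FALSE)
  raw <- rowMeans(freq) * rowMeans(int)
  data.frame(
    trial_id = if ("trial_id" %in% names(records)) records$trial_id
               else seq_len(nrow(records)),
    raw = raw,
    transformed = log1p(raw)
  )
}

#' Sample skewness and excess kurtosis
#'
#' Fisher-Pearson moment coefficients on population (biased) moments:
#' skewness `m3 / m2^1.5` and excess kurtosis `m4 / m2^2 - 3`. These are the
#' conventions under which a unimodal right-skewed score can show negative
#' kurtosis.
#'
#' @param x Numeric vector, length >= 3, finite, non-constant.
#' @return Named numeric vector `c(skewness, kurtosis)` (kurtosis = excess).
#' @export
distribution_stats <- function(x) {
  if (length(x) < 3 || any(!is.finite(x)))
    stop("need at least 3 finite values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: skewness/kurtosis undefined", call. = FALSE)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

#' Quality control: are facial scores explained by pain ratings?
#'
#' Fits `transformed FACS ~ rating` with per-subject random intercepts and
#' random rating slopes (REML, Satterthwaite degrees of freedom). If the
#' random-slope fit is singular it falls back to random intercepts only and
#' flags the result. At constant stimulus intensity the expectation is a
#' null association: spontaneous fluctuations of facial expression are not
#' driven by the rating report.
#'
#' @param facs Transformed FACS scores (one per trial).
#' @param ratings Pain ratings on the 0-100 scale, aligned with `facs`.
#' @param groups Subject identifier per trial.
#' @return A `mixed_model_result` with the rating slope, its confidence
#'   interval, t, Satterthwaite df, p, and marginal/conditional R2.
#' @export
qc_rating_association <- function(facs, ratings, groups) {
  stopifnot(length(facs) == length(ratings), length(facs) == length(groups))
  d <- data.frame(facs = facs, rating = ratings, subject = factor(groups))
  if (nlevels(d$subject) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  fit <- fit_lmm(facs ~ rating + (1 + rating | subject), d,
                 fallback = facs ~ rating + (1 | subject))
  new_mixed_result(fit)
}

#' Quality control: habituation / sensitization over trials and runs
#'
#' Fits `outcome ~ trial + run + trial:run` with per-subject random
#' intercepts. A non-null trial or run slope indicates drift of facial
#' expressivity (or of ratings) across the session.
#'
#' @param outcome Per-trial outcome (transformed FACS scores or ratings).
#' @param trial Trial index within run.
#' @param run Run index.
#' @param groups Subject identifier per trial.
#' @return A `mixed_model_result` reporting the trial, run and interaction
#'   terms.
#' @export
qc_habituation <- function(outcome, trial, run, groups) {
  stopifnot(length(outcome) == length(trial), length(outcome) == length(run),
            length(outcome) == length(groups))
  d <- data.frame(y = outcome, trial = as.numeric(trial),
                  run = as.numeric(run), subject = factor(groups))
  if (nlevels(d$subject) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  fit <- fit_lmm(y ~ trial * run + (1 | subject), d)
  new_mixed_result(fit)
}
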