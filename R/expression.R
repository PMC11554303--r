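#' Pattern expression of an activation map
#'
#' The expression score of a trial with respect to a signature is the dot
#' product of the activation map with the signature weight map over the
#' voxels present in both masks (voxels missing from either mask contribute
#' nothing). The score is linear in the activation map.
#'
#' @param map Activation [volume_map()].
#' @param signature Signature weight [volume_map()].
#' @return Numeric scalar score.
#' @export
compute_expression <- function(map, signature) {
  stop_if_misaligned(map, signature, "activation map and signature")
  joint <- map$mask & signature$mask
  sum(map$values[joint] * signature$values[joint])
}

#' Expression scores for a set of trial maps
#'
#' Vectorised [compute_expression()] over a `trial_maps` container.
#'
#' @param maps `trial_maps` container (see [simulate_trials()]).
#' @param signature Signature [volume_map()] aligned with the container grid.
#' @return Data frame with `trial_id` and `score`.
#' @export
expression_scores <- function(maps, signature) {
  stopifnot(inherits(maps, "trial_maps"))
  stop_if_misaligned(maps$ref, signature, "trial grid and signature")
  joint <- maps$ref$mask & signature$mask
  keep <- joint[maps$ref$mask]              # columns of the trial matrix
  w <- signature$values[maps$ref$mask] * keep
  data.frame(trial_id = maps$trial_id,
             score = as.numeric(maps$data %*% w))
}

#' Correlate expression scores with facial scores
#'
#' Pearson correlation with a two-sided t-test p-value and a 95% confidence
#' interval from the Fisher z-transform,
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`.
#'
#' @param scores Expression scores.
#' @param facs Facial (FACS composite) scores, aligned.
#' @return List with `r`, `p`, `ci` (length 2), `n`.
#' @export
correlate_expression <- function(scores, facs) {
  stopifnot(length(scores) == length(facs))
  n <- length(scores)
  if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(facs) == 0)
    stop("zero variance input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(scores, facs, method = "pearson")
  r <- unname(ct$estimate)
  z <- atanh(r)
  hw <- 1.96 / sqrt(n - 3)
  list(r = r, p = ct$p.value, ci = tanh(c(z - hw, z + hw)), n = n)
}

#' Stratify trial conditions by facial response
#'
#' Relabels pain trials according to whether any facial response occurred,
#' giving the three levels used in the condition contrasts: `warm`,
#' `pain_facs0` (pain without facial response) and `pain_facs_pos`.
#'
#' @param condition Character vector of `"pain"` / `"warm"`.
#' @param facs_raw Raw FACS composite per trial.
#' @return Factor with levels `warm`, `pain_facs0`, `pain_facs_pos`.
#' @export
stratify_pain_by_facs <- function(condition, facs_raw) {
  stopifnot(length(condition) == length(facs_raw))
  lab <- ifelse(condition == "warm", "warm",
                ifelse(facs_raw > 0, "pain_facs_pos", "pain_facs0"))
  factor(lab, levels = c("warm", "pain_facs0", "pain_facs_pos"))
}

#' Condition contrasts on expression scores
#'
#' Fits a linear mixed model `score ~ condition` with a random intercept per
#' subject, then compares the conditions through all pairwise contrasts on
#' the estimated marginal means with Tukey multiplicity adjustment. Each
#' contrast is accompanied by a standardised effect size: the EMM difference
#' divided by the square root of the summed random-effect and residual
#' variances ("total SD" convention).
#'
#' @param scores Expression scores per trial.
#' @param condition Condition labels (2 or more levels; e.g. output of
#'   [stratify_pain_by_facs()] or plain pain/warm).
#' @param groups Subject identifier per trial.
#' @return A list of class `condition_contrast_result`: `contrasts` (data
#'   frame with estimate, SE, df, t, Tukey-adjusted p, 95% CI, Cohen's d),
#'   `emmeans` (estimated marginal mean per condition), and `model`.
#' @export
condition_contrast <- function(scores, condition, groups) {
  stopifnot(length(scores) == length(condition), length(scores) == length(groups))
  d <- data.frame(score = scores, condition = factor(condition),
                  subject = factor(groups))
  d <- droplevels(d)
  if (nlevels(d$condition) < 2)
    stop("need at least 2 condition levels", call. = FALSE)
  if (nlevels(d$subject) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  small <- table(d$condition) < 2
  if (any(small))
    warning("condition level(s) with fewer than 2 observations: ",
            paste(names(which(small)), collapse = ", "))
  fit <- fit_lmm(score ~ condition + (1 | subject), d)
  m <- fit$model
  emm <- emmeans::emmeans(m, ~condition)
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  tab <- as.data.frame(summary(prs))
  ci <- as.data.frame(stats::confint(prs))
  total_sd <- sqrt(sum(unlist(lapply(lme4::VarCorr(m),
                                     function(g) diag(as.matrix(g))))) +
                   stats::sigma(m)^2)
  contrasts <- data.frame(
    contrast = tab$contrast,
    emm_difference = tab$estimate,
    se = tab$SE,
    df = tab$df,
    t = tab$t.ratio,
    p = tab$p.value,
    ci_lo = ci$lower.CL,
    ci_hi = ci$upper.CL,
    cohens_d = tab$estimate / total_sd
  )
  structure(
    list(contrasts = contrasts,
         emmeans = as.data.frame(summary(emm)),
         total_sd = total_sd,
         model = m),
    class = "condition_contrast_result"
  )
}

#' @export
print.condition_contrast_result <- function(x, ...) {
  cat("<condition_contrast_result>\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Cohen's d for two independent samples
#'
#' Classical standardised mean difference `(mean(x) - mean(y)) / s_pooled`
#' with the pooled (unbiased-variance) standard deviation.
#'
#' @param x,y Numeric samples.
#' @return Numeric scalar.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Quality control: facial scores from expression scores and ratings
#'
#' Fits `FACS ~ expression + rating + expression:rating` with per-subject
#' random intercepts and random slopes for both predictors; on a singular
#' fit it falls back to random intercepts only (flagged). Both predictors
#' are mean-centred before fitting so the interaction does not alias the
#' main effects (ratings live on a 0-100 scale); slopes are unchanged by
#' centring, and main effects are interpreted at the mean of the other
#' predictor. A signature that
#' captures facial expression beyond the rating report shows a significant
#' expression term with a null rating term.
#'
#' @param facs Transformed FACS scores per trial.
#' @param expression Signature expression scores per trial.
#' @param ratings Pain ratings per trial.
#' @param groups Subject identifier per trial.
#' @return A `mixed_model_result`.
#' @export
qc_feps_vs_ratings <- function(facs, expression, ratings, groups) {
  stopifnot(length(facs) == length(expression),
            length(facs) == length(ratings),
            length(facs) == length(groups))
  if (stats::sd(expression) == 0)
    stop("zero variance in expression scores: slope undefined", call. = FALSE)
  # predictors are mean-centred so the interaction term does not swamp the
  # main effects with collinearity (ratings live on a 0-100 scale)
  d <- data.frame(facs = facs,
                  expr = expression - mean(expression),
                  rating = ratings - mean(ratings),
                  subject = factor(groups))
  if (nlevels(d$subject) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (stats::sd(ratings) == 0) {
    fit <- fit_lmm(facs ~ expr + (1 + expr | subject), d,
                   fallback = facs ~ expr + (1 | subject))
  } else {
    fit <- fit_lmm(facs ~ expr * rating + (1 + expr + rating | subject), d,
                   fallback = facs ~ expr * rating + (1 | subject))
  }
  new_mixed_result(fit)
}
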