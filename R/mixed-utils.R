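# Shared machinery for the linear mixed models used in behavioral QC and
# condition contrasts: REML fits with Satterthwaite degrees of freedom,
# singular-fit fallback to a simpler random structure, and marginal /
# conditional R2 by the Nakagawa-Schielzeth variance decomposition.

fit_lmm <- function(formula, data, fallback = NULL) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  m <- suppressWarnings(suppressMessages(
    lmerTest::lmer(formula, data = data, REML = TRUE, control = ctrl)))
  fellback <- FALSE
  if (lme4::isSingular(m, tol = 1e-4) && !is.null(fallback)) {
    m <- suppressWarnings(suppressMessages(
      lmerTest::lmer(fallback, data = data, REML = TRUE, control = ctrl)))
    fellback <- TRUE
  }
  list(model = m, singular_fallback = fellback)
}

tidy_fixed <- function(m, level = 0.95) {
  cf <- stats::coef(summary(m))
  alpha <- 1 - level
  df <- cf[, "df"]
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  crit <- stats::qt(1 - alpha / 2, df)
  data.frame(
    term = rownames(cf),
    estimate = est,
    se = se,
    ci_lo = est - crit * se,
    ci_hi = est + crit * se,
    t = cf[, "t value"],
    df = df,
    p = cf[, "Pr(>|t|)"],
    row.names = NULL
  )
}

# Random-effect variance contribution for R2: for each variance component
# block G (per grouping factor) the average of x_i' G x_i over observations,
# with x_i the row of the corresponding term design matrix (Johnson's
# extension of Nakagawa-Schielzeth to random slopes).
ranef_variance <- function(m) {
  X <- stats::model.matrix(m)
  vc <- lme4::VarCorr(m)
  out <- numeric(0)
  for (g in seq_along(vc)) {
    G <- as.matrix(vc[[g]])
    terms <- rownames(G)
    miss <- setdiff(terms, colnames(X))
    if (length(miss))
      stop("random-effect term(s) not in fixed design: ",
           paste(miss, collapse = ", "), call. = FALSE)
    Xg <- X[, terms, drop = FALSE]
    out[g] <- mean(rowSums((Xg %*% G) * Xg))
    names(out)[g] <- names(vc)[g]
  }
  out
}

r2_glmm <- function(m) {
  var_fixed <- stats::var(as.numeric(
    stats::model.matrix(m) %*% lme4::fixef(m)))
  var_rand <- sum(ranef_variance(m))
  var_resid <- stats::sigma(m)^2
  tot <- var_fixed + var_rand + var_resid
  c(marginal = var_fixed / tot, conditional = (var_fixed + var_rand) / tot)
}

new_mixed_result <- function(fit) {
  m <- fit$model
  r2 <- r2_glmm(m)
  vc <- lme4::VarCorr(m)
  rv <- c(unlist(lapply(vc, function(g) diag(as.matrix(g)))),
          residual = stats::sigma(m)^2)
  structure(
    list(
      fixed_effects = tidy_fixed(m),
      marginal_r2 = unname(r2["marginal"]),
      conditional_r2 = unname(r2["conditional"]),
      random_effect_variances = rv,
      singular_fallback = fit$singular_fallback,
      model = m
    ),
    class = "mixed_model_result"
  )
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result>\n")
  print(x$fixed_effects, digits = 4)
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f%s\n",
              x$marginal_r2, x$conditional_r2,
              if (x$singular_fallback) "  [singular fit: simplified random structure]" else ""))
  invisible(x)
}
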