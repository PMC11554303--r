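#' Assemble a training dataset from maps and behavior
#'
#' Produces the trials x in-mask-voxels matrix the decoder consumes: one row
#' per retained trial of the requested condition, columns in the package's
#' fixed linear scan order of in-mask voxels (column-major over the grid),
#' outcome = transformed FACS score, grouping = subject.
#'
#' @param maps `trial_maps` container holding one activation map per
#'   generated trial.
#' @param behavior Output of [facs_scores()] (needs `trial_id`,
#'   `transformed`).
#' @param records Retained behavioral records (e.g. from
#'   [apply_exclusions()]); only rows of `condition` are used.
#' @param mask Optional [volume_map()] restricting the voxel set; defaults
#'   to the container's brain mask.
#' @param condition Condition to keep (default `"pain"`).
#' @return A list of class `training_dataset`: `X`, `y`, `groups`,
#'   `trial_id`, `voxel_index` (n_voxels x 3 grid coordinates), `mask_ref`.
#' @export
build_dataset <- function(maps, behavior, records, mask = NULL,
                          condition = "pain") {
  stopifnot(inherits(maps, "trial_maps"))
  keep_rec <- records[records$condition %in% condition &
                        !records$excluded, , drop = FALSE]
  if (nrow(keep_rec) == 0) stop("no retained trials of condition ",
                                paste(condition, collapse = "/"), call. = FALSE)
  row_idx <- match(keep_rec$trial_id, maps$trial_id)
  if (anyNA(row_idx))
    stop("behavioral rows without activation map, trial_id: ",
         paste(keep_rec$trial_id[is.na(row_idx)], collapse = ", "),
         call. = FALSE)
  y_idx <- match(keep_rec$trial_id, behavior$trial_id)
  if (anyNA(y_idx))
    stop("trials without behavioral score, trial_id: ",
         paste(keep_rec$trial_id[is.na(y_idx)], collapse = ", "),
         call. = FALSE)

  ref <- maps$ref
  if (is.null(mask)) {
    keep_col <- rep(TRUE, sum(ref$mask))
    mask_ref <- ref
  } else {
    stop_if_misaligned(ref, mask, "trial grid and mask")
    joint <- ref$mask & mask$mask & (mask$values != 0 | !is.numeric(mask$values))
    if (!any(joint)) stop("empty mask", call. = FALSE)
    keep_col <- joint[ref$mask]
    mask_ref <- volume_map(array(0, dim(ref$values)), affine = ref$affine,
                           mask = joint, name = "dataset_mask")
  }
  X <- maps$data[row_idx, keep_col, drop = FALSE]
  if (any(apply(X, 2, stats::sd) == 0))
    warning("dataset contains constant voxel column(s) inside the mask")
  structure(
    list(
      X = X,
      y = behavior$transformed[y_idx],
      groups = as.character(keep_rec$subject),
      trial_id = keep_rec$trial_id,
      voxel_index = which(mask_ref$mask, arr.ind = TRUE),
      mask_ref = mask_ref
    ),
    class = "training_dataset"
  )
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf("<training_dataset> %d trials x %d voxels, %d subjects\n",
              nrow(x$X), ncol(x$X), length(unique(x$groups))))
  invisible(x)
}

#' Restrict a training dataset to a region of interest
#'
#' Keeps only the columns whose voxels fall inside both the dataset mask and
#' the ROI (nonzero / TRUE voxels of `roi`), updating the voxel index.
#'
#' @param ds A `training_dataset`.
#' @param roi [volume_map()] aligned with the dataset mask; nonzero voxels
#'   define the region.
#' @return A `training_dataset` on the restricted voxel set.
#' @export
restrict_to_roi <- function(ds, roi) {
  stopifnot(inherits(ds, "training_dataset"))
  stop_if_misaligned(ds$mask_ref, roi, "dataset mask and ROI")
  joint <- ds$mask_ref$mask & roi$mask & roi$values != 0
  if (!any(joint)) stop("ROI does not intersect the dataset mask", call. = FALSE)
  keep_col <- joint[ds$mask_ref$mask]
  new_mask <- volume_map(array(0, dim(ds$mask_ref$values)),
                         affine = ds$mask_ref$affine, mask = joint,
                         name = "roi_mask")
  structure(
    list(X = ds$X[, keep_col, drop = FALSE],
         y = ds$y, groups = ds$groups, trial_id = ds$trial_id,
         voxel_index = which(joint, arr.ind = TRUE),
         mask_ref = new_mask),
    class = "training_dataset"
  )
}

# L1-penalised regression of y on principal-component scores. `scores` must
# be column-centred (they are, coming from an SVD of a centred matrix).
# Returns the component coefficients and intercept. glmnet solves
# (1/2n)||y - b0 - S b||^2 + penalty * ||b||_1, the same objective the fixed
# penalty refers to.
lasso_on_scores <- function(scores, y, penalty) {
  n <- nrow(scores)
  r <- ncol(scores)
  lmax <- max(abs(crossprod(scores, y - mean(y)))) / n
  if (penalty >= lmax || r == 0) {
    return(list(beta = rep(0, r), intercept = mean(y), n_nonzero = 0L))
  }
  if (r == 1) {
    s <- scores[, 1]
    bls <- sum(s * (y - mean(y))) / n
    ss <- sum(s^2) / n
    b <- sign(bls) * max(0, abs(bls) - penalty) / ss
    return(list(beta = b, intercept = mean(y), n_nonzero = as.integer(b != 0)))
  }
  lambda <- exp(seq(log(lmax), log(penalty), length.out = 30))
  fit <- glmnet::glmnet(scores, y, alpha = 1, lambda = lambda,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12)
  cf <- stats::coef(fit, s = penalty)
  beta <- as.numeric(cf)[-1]
  list(beta = beta, intercept = as.numeric(cf)[1],
       n_nonzero = sum(beta != 0))
}

#' Fit a LASSO principal-component regression signature
#'
#' Columns of `X` are centred by their training means; the centred matrix is
#' decomposed by SVD, retaining every component with a nonzero singular
#' value (at most `n - 1`); an L1-penalised linear regression with fixed
#' penalty weight is fit on the (unstandardised) component scores with an
#' intercept; and the component coefficients are back-projected to voxel
#' space. The prediction rule is
#' `yhat(x) = (x - column_means) . weights + intercept`, so predicting the
#' training-mean map returns the training-mean outcome.
#'
#' @param X Trials x voxels matrix (or a `training_dataset`).
#' @param y Outcome vector (ignored when `X` is a `training_dataset`).
#' @param penalty L1 penalty weight (the "alpha" of the canonical LASSO-PCR
#'   formulation); default 1.0.
#' @return A list of class `signature_model`: `weights` (voxel vector),
#'   `weight_map` ([volume_map()] when a dataset was supplied), `intercept`,
#'   `column_means`, `n_components_retained`, `n_nonzero_components`,
#'   `penalty`.
#' @export
fit_lasso_pcr <- function(X, y = NULL, penalty = 1) {
  ds <- NULL
  if (inherits(X, "training_dataset")) {
    ds <- X
    y <- ds$y
    X <- ds$X
  }
  stopifnot(is.matrix(X), length(y) == nrow(X), penalty > 0)
  if (nrow(X) < 3) stop("need at least 3 training rows", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  V <- sv$v[, seq_len(r), drop = FALSE]
  fit <- lasso_on_scores(scores, y, penalty)
  if (fit$n_nonzero == 0)
    warning("penalty shrank all component coefficients to zero; model predicts the training mean")
  w <- as.numeric(V %*% fit$beta)
  weight_map <- if (!is.null(ds))
    embed_values(w, ds$mask_ref, name = "signature_weights") else NULL
  structure(
    list(weights = w, weight_map = weight_map,
         intercept = fit$intercept, column_means = mu,
         n_components_retained = r,
         n_nonzero_components = fit$n_nonzero,
         penalty = penalty),
    class = "signature_model"
  )
}

#' Predict from a fitted signature model
#'
#' @param object A `signature_model`.
#' @param newdata Matrix of trials x voxels (same column order as training),
#'   a `training_dataset`, or a single [volume_map()] (requires the model to
#'   carry a weight map).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.signature_model <- function(object, newdata, ...) {
  if (inherits(newdata, "training_dataset")) newdata <- newdata$X
  if (inherits(newdata, "volume_map")) {
    if (is.null(object$weight_map))
      stop("model carries no weight map; supply a matrix instead", call. = FALSE)
    stop_if_misaligned(newdata, object$weight_map, "map and weight map")
    x <- newdata$values[object$weight_map$mask]
    return(sum((x - object$column_means) * object$weights) + object$intercept)
  }
  stopifnot(is.matrix(newdata), ncol(newdata) == length(object$weights))
  as.numeric(sweep(newdata, 2, object$column_means) %*% object$weights) +
    object$intercept
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d voxels, %d components (%d nonzero), penalty %.3g\n",
              length(x$weights), x$n_components_retained,
              x$n_nonzero_components, x$penalty))
  invisible(x)
}

# ---- shared-basis machinery -------------------------------------------------
#
# Cross-validation, permutation and bootstrap refit the same model on row
# subsets / reweightings of one matrix. Every such subset lives in the row
# space of the full matrix, so we express all rows once in the basis of the
# full data's right singular vectors and refit in that (n-dimensional)
# coordinate space; voxel-space weights are recovered by one back-projection.
# This is algebraically exact and avoids repeated voxel-dimension SVDs.

pcr_basis <- function(X) {
  mu0 <- colMeans(X)
  Xc <- sweep(X, 2, mu0)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d)
  r <- sum(sv$d > tol)
  list(
    mu0 = mu0,
    V = sv$v[, seq_len(r), drop = FALSE],
    S = sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  )
}

# Fit LASSO-PCR on rows `idx` (with repetition allowed) expressed in the
# shared basis; returns coordinate-space weights and the pieces needed to
# predict other rows.
pcr_fit_coords <- function(basis, idx, y, penalty) {
  Sb <- basis$S[idx, , drop = FALSE]
  mu_s <- colMeans(Sb)
  Sc <- sweep(Sb, 2, mu_s)
  sv <- svd(Sc)
  tol <- max(dim(Sc)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  W <- sv$v[, seq_len(r), drop = FALSE]
  fit <- lasso_on_scores(scores, y[idx], penalty)
  list(beta_coord = as.numeric(W %*% fit$beta),
       mu_s = mu_s, intercept = fit$intercept,
       n_nonzero = fit$n_nonzero)
}

pcr_predict_coords <- function(basis, fit, idx) {
  Sn <- basis$S[idx, , drop = FALSE]
  as.numeric(sweep(Sn, 2, fit$mu_s) %*% fit$beta_coord) + fit$intercept
}

# -----------------------------------------------------------------------------

make_group_folds <- function(groups, k, seed) {
  subjects <- unique(groups)
  if (k > length(subjects))
    stop("k exceeds the number of subjects", call. = FALSE)
  shuffled <- withr::with_seed(seed, sample(subjects))
  fold_of_subject <- rep(seq_len(k), length.out = length(shuffled))
  split(shuffled, fold_of_subject)
}

fold_metrics <- function(y, pred) {
  r <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(y, pred)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((y - pred)^2) / ss_tot
  rmse <- sqrt(mean((y - pred)^2))
  c(r = r, r2 = r2, rmse = rmse)
}

cv_run <- function(basis, y, groups, folds, penalty) {
  per_fold <- vector("list", length(folds))
  pooled <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- which(groups %in% folds[[f]])
    train <- setdiff(seq_along(y), test)
    fit <- pcr_fit_coords(basis, train, y, penalty)
    pred <- pcr_predict_coords(basis, fit, test)
    m <- fold_metrics(y[test], pred)
    per_fold[[f]] <- data.frame(fold = f, n_test = length(test),
                                r = m["r"], r2 = m["r2"], rmse = m["rmse"],
                                row.names = NULL)
    pooled[[f]] <- data.frame(row = test, fold = f, y = y[test], pred = pred)
  }
  list(per_fold = do.call(rbind, per_fold), pooled = do.call(rbind, pooled))
}

#' Participant-grouped k-fold cross-validation of LASSO-PCR
#'
#' Subjects are shuffled (seeded) and dealt round-robin into `k` folds, so
#' every trial of a given participant sits entirely in the training or the
#' testing side of each split. Per fold the model is refit on the training
#' subjects and evaluated on the held-out subjects with Pearson r,
#' coefficient of determination `1 - SS_res/SS_tot` computed on the test
#' fold (negative when the model underperforms the test-fold mean), and
#' RMSE.
#'
#' @param ds A `training_dataset`.
#' @param k Number of folds (default 10).
#' @param penalty L1 penalty weight (default 1.0).
#' @param seed Seed controlling the fold assignment.
#' @return A list of class `cv_result`: `per_fold` (metrics per fold),
#'   `summary` (mean and SD per metric), `pooled` (held-out predictions),
#'   `folds` (test-subject lists).
#' @export
cross_validate <- function(ds, k = 10, penalty = 1, seed = 1L) {
  stopifnot(inherits(ds, "training_dataset"))
  folds <- make_group_folds(ds$groups, k, seed)
  basis <- pcr_basis(ds$X)
  res <- cv_run(basis, ds$y, ds$groups, folds, penalty)
  pf <- res$per_fold
  summary <- data.frame(
    metric = c("r", "r2", "rmse"),
    mean = c(mean(pf$r, na.rm = TRUE), mean(pf$r2), mean(pf$rmse)),
    sd = c(stats::sd(pf$r, na.rm = TRUE), stats::sd(pf$r2), stats::sd(pf$rmse))
  )
  structure(
    list(per_fold = pf, summary = summary, pooled = res$pooled,
         folds = folds, k = k, penalty = penalty, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", x$k))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Permutation test of cross-validated decoding performance
#'
#' Re-runs the full grouped cross-validation with the outcome permuted
#' across all trials, `n_perm` times, and compares the observed mean fold
#' statistic against the null distribution with the add-one convention
#' `p = (#\{null >= observed\} + 1) / (n_perm + 1)`.
#'
#' @param ds A `training_dataset`.
#' @param k,penalty,seed As in [cross_validate()]; the observed statistic
#'   and every permutation reuse the same fold assignment.
#' @param n_perm Number of outcome permutations.
#' @param statistic `"r2"` (mean fold coefficient of determination, the
#'   default) or `"r"` (mean fold Pearson r).
#' @return A list of class `permutation_result`: `observed`, `null_scores`,
#'   `p`, `statistic`.
#' @export
permutation_test <- function(ds, k = 10, penalty = 1, n_perm = 200,
                             seed = 1L, statistic = c("r2", "r")) {
  stopifnot(inherits(ds, "training_dataset"), n_perm >= 1)
  statistic <- match.arg(statistic)
  folds <- make_group_folds(ds$groups, k, seed)
  basis <- pcr_basis(ds$X)
  stat_of <- function(pf) mean(pf[[statistic]], na.rm = TRUE)
  observed <- stat_of(cv_run(basis, ds$y, ds$groups, folds, penalty)$per_fold)
  null_scores <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_perm), function(b) {
      y_perm <- sample(ds$y)
      stat_of(cv_run(basis, y_perm, ds$groups, folds, penalty)$per_fold)
    }, numeric(1))
  })
  p <- add_one_pvalue(null_scores, observed)
  structure(
    list(observed = observed, null_scores = null_scores, p = p,
         statistic = statistic, n_perm = n_perm),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %s = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Bootstrap inference on voxel weights
#'
#' Resamples the dataset with replacement to its original size, refits the
#' LASSO-PCR on each resample, and summarises the per-voxel weight
#' distribution as `z = bootstrap mean / bootstrap SD` with a two-sided
#' normal p-value. Voxels with zero bootstrap SD are flagged and assigned
#' p = 1. The default resampling unit is the trial, matching a resample of
#' "the same number of observations"; `unit = "subject"` resamples whole
#' participants instead.
#'
#' @param ds A `training_dataset`.
#' @param penalty L1 penalty weight.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param unit `"trial"` (default) or `"subject"`.
#' @return A list of class `bootstrap_result`: `z`, `p` (voxel vectors),
#'   `z_map`, `p_map` ([volume_map()]s), `mean_weights`, `sd_weights`,
#'   `n_flagged` (zero-SD voxels), `n_boot`.
#' @export
bootstrap_weights <- function(ds, penalty = 1, n_boot = 200, seed = 1L,
                              unit = c("trial", "subject")) {
  stopifnot(inherits(ds, "training_dataset"), n_boot >= 2)
  unit <- match.arg(unit)
  basis <- pcr_basis(ds$X)
  n <- nrow(ds$X)
  subjects <- unique(ds$groups)
  W <- matrix(0, ncol(ds$X), n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- if (unit == "trial") {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(lapply(sample(subjects, length(subjects), replace = TRUE),
                      function(s) which(ds$groups == s)), use.names = FALSE)
      }
      fit <- pcr_fit_coords(basis, idx, ds$y, penalty)
      W[, b] <- as.numeric(basis$V %*% fit$beta_coord)
    }
  })
  mw <- rowMeans(W)
  sw <- apply(W, 1, stats::sd)
  z <- rep(NA_real_, length(mw))
  ok <- sw > 0
  z[ok] <- mw[ok] / sw[ok]
  p <- rep(1, length(mw))
  p[ok] <- 2 * stats::pnorm(-abs(z[ok]))
  structure(
    list(z = z, p = p,
         z_map = embed_values(ifelse(ok, z, 0), ds$mask_ref, "bootstrap_z"),
         p_map = embed_values(p, ds$mask_ref, "bootstrap_p"),
         mean_weights = mw, sd_weights = sw,
         n_flagged = sum(!ok), n_boot = n_boot, unit = unit),
    class = "bootstrap_result"
  )
}

#' Benjamini-Hochberg threshold of a voxel p-map
#'
#' Applies the step-up false-discovery-rate procedure over the in-mask
#' p-values and returns the survival mask.
#'
#' @param p_map [volume_map()] of p-values (or a bare numeric vector).
#' @param q FDR level.
#' @return A [volume_map()] whose values are 1 where the voxel survives
#'   (with the same mask), or a logical vector when `p_map` is a vector.
#' @export
threshold_fdr <- function(p_map, q = 0.05) {
  if (is.numeric(p_map) && is.null(dim(p_map))) {
    stopifnot(all(p_map >= 0 & p_map <= 1))
    return(stats::p.adjust(p_map, method = "BH") <= q)
  }
  stopifnot(inherits(p_map, "volume_map"))
  p <- mask_values(p_map)
  stopifnot(all(p >= 0 & p <= 1))
  surv <- stats::p.adjust(p, method = "BH") <= q
  embed_values(as.numeric(surv), p_map, name = sprintf("fdr_q%.3g", q))
}

#' Corrected resampled t-test for model comparison
#'
#' For per-fold performance differences `d_1..d_J` between two models
#' evaluated on the same resampling splits, the statistic is
#' `t = mean(d) / sqrt((1/J + n_test/n_train) * var(d))` with `J - 1`
#' degrees of freedom. The variance inflation by `n_test/n_train` accounts
#' for the overlap of training sets across folds; as `n_test/n_train -> 0`
#' the classical one-sample t-test on fold differences is recovered.
#'
#' @param diffs Per-fold performance differences.
#' @param n_train,n_test Training and testing set sizes per split.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return A list of class `model_comparison`: `t`, `df`, `p`, `mean_diff`,
#'   and a `note` when fold differences are exactly tied.
#' @export
corrected_resampled_ttest <- function(diffs, n_train, n_test,
                                      alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  J <- length(diffs)
  stopifnot(J >= 2, n_train > 0, n_test > 0)
  md <- mean(diffs)
  v <- stats::var(diffs)
  note <- NULL
  if (v == 0) {
    note <- "zero variance of fold differences (exact ties)"
    t_stat <- if (md == 0) 0 else sign(md) * Inf
  } else {
    t_stat <- md / sqrt((1 / J + n_test / n_train) * v)
  }
  df <- J - 1
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t_stat), df),
    greater = stats::pt(t_stat, df, lower.tail = FALSE),
    less = stats::pt(t_stat, df)
  )
  structure(list(t = t_stat, df = df, p = p, mean_diff = md,
                 alternative = alternative, note = note),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> t(%d) = %.3f, p = %.4g (%s)\n",
              x$df, x$t, x$p, x$alternative))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
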