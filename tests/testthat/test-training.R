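# deterministic linear testbed: y realisable from X through a sparse pattern
make_linear_testbed <- function(n = 60, p = 150, n_subj = 10, noise = 0,
                                seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    w <- numeric(p); w[1:10] <- seq(1, 0.1, length.out = 10)
    y <- as.numeric(X %*% w) + rnorm(n, 0, noise)
    groups <- rep(sprintf("s%d", seq_len(n_subj)), length.out = n)
    list(X = X, y = y, w = w, groups = groups)
  })
}

test_that("dataset assembly aligns maps, behavior and exclusions", {
  fx <- get_small_sim()
  cfg <- fx$cfg
  ret <- apply_exclusions(fx$sim$records, cfg)
  sc <- facs_scores(fx$sim$records)
  ds <- build_dataset(fx$sim$maps, sc, ret)
  n_expect <- cfg$n_subjects * cfg$trials_per_condition - cfg$n_excluded_pain
  expect_equal(nrow(ds$X), n_expect)
  expect_equal(ncol(ds$X), sum(fx$sim$maps$ref$mask))
  expect_equal(length(ds$y), nrow(ds$X))

  # voxel_index round-trips to the scan order of in-mask voxels
  lin <- which(ds$mask_ref$mask)
  j <- c(1, 17, ncol(ds$X))
  coord <- ds$voxel_index[j, , drop = FALSE]
  lin_back <- coord[, 1] +
    (coord[, 2] - 1) * dim(ds$mask_ref$values)[1] +
    (coord[, 3] - 1) * prod(dim(ds$mask_ref$values)[1:2])
  expect_equal(match(lin_back, lin), j)

  # missing map rows are reported with the offending trials
  broken <- ret[1:5, ]
  broken$trial_id[1] <- 99999L
  expect_error(build_dataset(fx$sim$maps, sc, broken), "99999")

  empty <- volume_map(array(0, dim(fx$sim$maps$ref$values)),
                      affine = fx$sim$maps$ref$affine,
                      mask = array(FALSE, dim(fx$sim$maps$ref$values)))
  expect_error(build_dataset(fx$sim$maps, sc, ret, mask = empty), "mask")
})

test_that("LASSO-PCR recovers a realizable linear target and shrinks fully", {
  tb <- make_linear_testbed(p = 30)
  train <- 1:40; test <- 41:60
  m <- fit_lasso_pcr(tb$X[train, ], tb$y[train], penalty = 1e-4)
  pred <- predict(m, tb$X[test, ])
  expect_gt(cor(pred, tb$y[test]), 0.99)

  # training-mean input predicts the training-mean outcome
  mu_pred <- predict(m, matrix(colMeans(tb$X[train, ]), 1))
  expect_equal(mu_pred, mean(tb$y[train]), tolerance = 1e-8)

  # penalty beyond lambda_max collapses to the constant predictor
  expect_warning(m0 <- fit_lasso_pcr(tb$X[train, ], tb$y[train],
                                     penalty = 1e6), "training mean")
  expect_equal(unique(round(predict(m0, tb$X[test, ]), 10)),
               round(mean(tb$y[train]), 10))
})

test_that("voxel-space weights reproduce component-space predictions", {
  tb <- make_linear_testbed(n = 40, p = 80, noise = 0.5)
  m <- fit_lasso_pcr(tb$X, tb$y, penalty = 0.05)

  # independent component-space path: centre, SVD, lasso on scores
  mu <- colMeans(tb$X)
  Xc <- sweep(tb$X, 2, mu)
  sv <- svd(Xc)
  r <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  scores <- sv$u[, 1:r] %*% diag(sv$d[1:r])
  fit <- glmnet::glmnet(scores, tb$y, alpha = 1, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12,
                        lambda = exp(seq(log(max(abs(crossprod(scores, tb$y - mean(tb$y)))) / nrow(scores)),
                                         log(0.05), length.out = 30)))
  cf <- as.numeric(coef(fit, s = 0.05))
  newX <- withr::with_seed(99, matrix(rnorm(50 * 80), 50, 80))
  pred_comp <- (sweep(newX, 2, mu) %*% sv$v[, 1:r]) %*% cf[-1] + cf[1]
  pred_vox <- predict(m, newX)
  expect_lt(max(abs(pred_vox - as.numeric(pred_comp))), 1e-8)
})

test_that("grouped folds partition subjects and never leak", {
  tb <- make_linear_testbed(noise = 1)
  X <- tb$X; y <- tb$y; groups <- tb$groups
  ds <- structure(list(X = X, y = y, groups = groups,
                       trial_id = seq_along(y),
                       voxel_index = NULL, mask_ref = NULL),
                  class = "training_dataset")
  cv <- cross_validate(ds, k = 5, penalty = 0.01, seed = 3)
  expect_setequal(unlist(cv$folds), unique(groups))
  expect_equal(sum(lengths(cv$folds)), length(unique(groups)))
  for (f in seq_along(cv$folds)) {
    test_rows <- cv$pooled$row[cv$pooled$fold == f]
    expect_true(all(groups[test_rows] %in% cv$folds[[f]]))
  }
  expect_error(cross_validate(ds, k = 50), "exceeds")

  # noise-free realisable target decodes nearly perfectly out of subject
  tb0 <- make_linear_testbed(p = 30, noise = 0)
  ds0 <- structure(list(X = tb0$X, y = tb0$y, groups = tb0$groups,
                        trial_id = seq_along(tb0$y),
                        voxel_index = NULL, mask_ref = NULL),
                   class = "training_dataset")
  cv0 <- cross_validate(ds0, k = 5, penalty = 1e-4, seed = 3)
  expect_gt(mean(cv0$per_fold$r), 0.99)
})

test_that("shared-basis CV refits agree with direct voxel-space refits", {
  tb <- make_linear_testbed(n = 50, p = 90, noise = 0.8, seed = 4)
  ds <- structure(list(X = tb$X, y = tb$y, groups = tb$groups,
                       trial_id = seq_along(tb$y),
                       voxel_index = NULL, mask_ref = NULL),
                  class = "training_dataset")
  cv <- cross_validate(ds, k = 5, penalty = 0.1, seed = 11)
  folds <- cv$folds
  for (f in c(1, 3)) {
    test <- which(tb$groups %in% folds[[f]])
    train <- setdiff(seq_along(tb$y), test)
    m <- fit_lasso_pcr(tb$X[train, ], tb$y[train], penalty = 0.1)
    pred_direct <- predict(m, tb$X[test, ])
    pred_cv <- cv$pooled$pred[cv$pooled$fold == f]
    expect_equal(pred_cv, pred_direct, tolerance = 1e-6)
  }
})

test_that("permutation p-values follow the add-one counting rule", {
  expect_equal(fepsig:::add_one_pvalue(c(0.10, 0.30, 0.05), 0.20), 0.5)
  expect_equal(fepsig:::add_one_pvalue(rnorm(99) - 10, 0.5), 1 / 100)
  expect_equal(fepsig:::add_one_pvalue(c(0.3, -0.5, 0.1), 0.4,
                                       two_sided = TRUE), 0.5)

  # an observed statistic beating every null lands at the floor 1/(n+1)
  tb <- make_linear_testbed(p = 30, noise = 0.1)
  ds <- structure(list(X = tb$X, y = tb$y, groups = tb$groups,
                       trial_id = seq_along(tb$y),
                       voxel_index = NULL, mask_ref = NULL),
                  class = "training_dataset")
  pr <- permutation_test(ds, k = 5, penalty = 1e-3, n_perm = 99, seed = 2)
  expect_equal(pr$p, 1 / 100)
  expect_length(pr$null_scores, 99)

  # reproducibility of the null distribution
  pr2 <- permutation_test(ds, k = 5, penalty = 1e-3, n_perm = 99, seed = 2)
  expect_identical(pr$null_scores, pr2$null_scores)
})

test_that("bootstrap weight inference flags degenerate voxels and ranks signal", {
  fx <- get_small_sim()
  cfg <- fx$cfg
  ret <- apply_exclusions(fx$sim$records, cfg)
  sc <- facs_scores(fx$sim$records)
  ds <- build_dataset(fx$sim$maps, sc, ret)
  bw <- bootstrap_weights(ds, penalty = 1, n_boot = 100, seed = 6)
  expect_length(bw$z, ncol(ds$X))
  ok <- bw$sd_weights > 0
  expect_equal(bw$p[ok], 2 * pnorm(-abs(bw$z[ok])), tolerance = 1e-12)
  expect_true(all(bw$p[!ok] == 1))
  expect_equal(bw$n_flagged, sum(!ok))

  truth <- mask_values(fx$sim$ground_truth$true_pattern)
  in_cluster <- truth != 0
  expect_gt(median(abs(bw$z[in_cluster])), median(abs(bw$z[!in_cluster])))

  # z = 1.96 corresponds to p ~ 0.05 under the normal reference
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)

  # determinism
  bw2 <- bootstrap_weights(ds, penalty = 1, n_boot = 100, seed = 6)
  expect_identical(bw$z, bw2$z)
})

test_that("BH thresholding matches hand and brute-force subset oracles", {
  expect_equal(sum(threshold_fdr(c(0.001, 0.01, 0.02, 0.04, 0.9), q = 0.05)), 4)
  expect_equal(sum(threshold_fdr(rep(1, 8), q = 0.05)), 0)
  expect_equal(sum(threshold_fdr(rep(0, 8), q = 0.05)), 8)

  # brute-force oracle: largest rejection count k such that at least k
  # p-values sit at or below k*q/m; reject exactly those
  bh_oracle <- function(p, q) {
    m <- length(p)
    for (k in m:0) {
      if (k == 0) return(rep(FALSE, m))
      thr <- k * q / m
      if (sum(p <= thr) >= k) return(p <= thr)
    }
  }
  withr::with_seed(13, {
    for (rep in 1:1000) {
      n <- sample(1:10, 1)
      p <- round(runif(n), 3)
      q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
      expect_identical(threshold_fdr(p, q), bh_oracle(p, q))
    }
  })

  # volume interface returns a survival mask on the same grid
  fx <- get_small_sim()
  ref <- fx$sim$maps$ref
  pm <- embed_values(runif(sum(ref$mask)), ref)
  surv <- threshold_fdr(pm, q = 0.05)
  expect_s3_class(surv, "volume_map")
  expect_true(all(surv$values %in% c(0, 1)))
})

test_that("ROI restriction subsets columns exactly and rejects empty overlap", {
  fx <- get_small_sim()
  ret <- apply_exclusions(fx$sim$records, fx$cfg)
  sc <- facs_scores(fx$sim$records)
  ds <- build_dataset(fx$sim$maps, sc, ret)
  ref <- ds$mask_ref

  full <- volume_map(array(1, dim(ref$values)), affine = ref$affine,
                     mask = ref$mask)
  ds_full <- restrict_to_roi(ds, full)
  expect_equal(ncol(ds_full$X), ncol(ds$X))

  half_vals <- array(0, dim(ref$values))
  half_vals[1:(dim(ref$values)[1] %/% 2), , ] <- 1
  half <- volume_map(half_vals, affine = ref$affine, mask = ref$mask)
  ds_half <- restrict_to_roi(ds, half)
  expect_equal(ncol(ds_half$X), sum(ref$mask & half_vals != 0))

  none <- volume_map(array(0, dim(ref$values)), affine = ref$affine,
                     mask = ref$mask)
  expect_error(restrict_to_roi(ds, none), "does not intersect")
})

test_that("corrected resampled t-test reproduces the hand-computed example", {
  res <- corrected_resampled_ttest(c(0.1, 0.2, 0.15, 0.05, 0.1),
                                   n_train = 4, n_test = 1)
  expect_equal(res$t, 0.12 / sqrt((1 / 5 + 1 / 4) * 0.00325), tolerance = 1e-12)
  expect_equal(res$t, 3.1378, tolerance = 1e-3)
  expect_equal(res$df, 4)

  res0 <- corrected_resampled_ttest(rep(0, 5), n_train = 4, n_test = 1)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_match(res0$note, "ties")

  # vanishing test/train ratio recovers the classical one-sample t
  d <- c(0.1, 0.2, 0.15, 0.05, 0.1)
  res_lim <- corrected_resampled_ttest(d, n_train = 1e9, n_test = 1)
  expect_equal(res_lim$t, unname(t.test(d)$statistic), tolerance = 1e-3)
})

test_that("whole-brain decoding beats an ROI missing part of the pattern", {
  diffs <- numeric(10)
  for (k in seq_len(10)) {
    cfg <- generator_config(n_subjects = 10, trials_per_condition = 6,
                            grid_shape = c(14, 16, 14), seed = 8000 + k)
    gt <- make_ground_truth(cfg)
    sim <- simulate_trials(cfg, gt)
    ret <- apply_exclusions(sim$records, cfg)
    sc <- facs_scores(sim$records)
    ds <- build_dataset(sim$maps, sc, ret)
    ref <- ds$mask_ref
    # ROI = one octant containing a single positive cluster; the other
    # three clusters lie outside it
    roi_vals <- array(0, dim(ref$values))
    d <- dim(ref$values)
    roi_vals[(d[1] %/% 2):d[1], (d[2] %/% 2):d[2], 1:(d[3] %/% 2)] <- 1
    roi <- volume_map(roi_vals, affine = ref$affine, mask = ref$mask)
    ds_roi <- restrict_to_roi(ds, roi)
    cv_full <- cross_validate(ds, k = 5, seed = k)
    cv_roi <- cross_validate(ds_roi, k = 5, seed = k)
    diffs[k] <- mean(cv_full$per_fold$r2) - mean(cv_roi$per_fold$r2)
  }
  expect_gt(mean(diffs), 0)
})
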