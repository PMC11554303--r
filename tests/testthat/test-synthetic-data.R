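test_that("ground-truth pattern is deterministic, sparse, signed, and masked", {
  cfg <- small_config()
  gt1 <- make_ground_truth(cfg)
  gt2 <- make_ground_truth(cfg)
  expect_identical(gt1$true_pattern$values, gt2$true_pattern$values)

  w <- gt1$true_pattern$values
  mask <- gt1$true_pattern$mask
  expect_true(all(w[!mask] == 0))
  expect_gt(max(w), 0)
  expect_lt(min(w), 0)
  frac <- mean(w[mask] != 0)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.30)

  expect_error(make_ground_truth(generator_config(grid_shape = c(6, 10, 10))),
               "grid too small")
})

test_that("zero smoothing returns the bare cluster stencil", {
  cfg <- small_config(smoothness_fwhm_mm = 0)
  gt <- make_ground_truth(cfg)
  vals <- unique(round(gt$true_pattern$values / max(abs(gt$true_pattern$values)), 10))
  # unsmoothed stencil holds only amplitude levels (0, +/-1 scaled)
  expect_true(all(abs(vals) %in% c(0, 1)))
})

test_that("simulation is deterministic and produces the designed trial counts", {
  cfg <- tiny_config()
  gt <- make_ground_truth(cfg)
  s1 <- simulate_trials(cfg, gt)
  s2 <- simulate_trials(cfg, gt)
  expect_identical(s1$maps$data, s2$maps$data)
  expect_identical(s1$records, s2$records)

  expect_equal(nrow(s1$records), cfg$n_subjects * cfg$trials_per_condition * 2)
  expect_equal(sum(s1$records$condition == "pain"),
               cfg$n_subjects * cfg$trials_per_condition)
  # intensity zero wherever frequency is zero
  for (au in c("AU4", "AU67", "AU910", "AU43")) {
    f <- s1$records[[paste0(au, "_freq")]]
    i <- s1$records[[paste0(au, "_int")]]
    expect_true(all(i[f == 0] == 0))
    expect_true(all(i[f > 0] > 0))
  }
  # warm ratings below the 50/100 pain threshold, pain ratings at or above
  expect_true(all(s1$records$rating[s1$records$condition == "warm"] < 50))
  expect_true(all(s1$records$rating[s1$records$condition == "pain"] >= 50))
})

test_that("AU integerisation recovers the target composite up to rounding", {
  targets <- c(0.3, 0.9, 1.5, 3.2, 7.7, 20, 45)
  for (r in targets) {
    au <- fepsig:::raw_to_au(r)
    got <- mean(au$freq) * mean(au$int)
    expect_lt(abs(got - r), 0.26)
    expect_true(all(au$int <= 5))
  }
  au0 <- fepsig:::raw_to_au(0)
  expect_true(all(au0$freq == 0) && all(au0$int == 0))
})

test_that("no effect size decouples facial scores from the latent signal", {
  cfg <- generator_config(n_subjects = 25, trials_per_condition = 12,
                          grid_shape = c(10, 10, 10), effect_size = 0,
                          zero_inflation_prob = 0, seed = 11)
  gt <- make_ground_truth(cfg)
  sim <- simulate_trials(cfg, gt)
  pain <- sim$records$condition == "pain"
  sc <- facs_scores(sim$records)
  proj <- expression_scores(sim$maps, gt$true_pattern)$score
  expect_gte(sum(pain), 300)
  expect_lt(abs(cor(sc$transformed[pain], proj[pain])), 0.1)
})

test_that("with vanishing noise the projection tracks the facial score", {
  cfg <- generator_config(n_subjects = 12, trials_per_condition = 10,
                          grid_shape = c(12, 12, 12), noise_sd = 1e-6,
                          subject_sd = 0, zero_inflation_prob = 0,
                          gamma_shape = 1e4, seed = 5)
  gt <- make_ground_truth(cfg)
  sim <- simulate_trials(cfg, gt)
  pain <- sim$records$condition == "pain"
  proj <- expression_scores(sim$maps, gt$true_pattern)$score[pain]
  z <- sim$ground_truth$latent_signal[pain]
  expect_gt(cor(proj, z), 0.99)
})

test_that("warm trials carry no loading on the true pattern", {
  fx <- get_small_sim()
  warm <- fx$sim$records$condition == "warm"
  proj <- expression_scores(fx$sim$maps,
                            fx$sim$ground_truth$true_pattern)$score[warm]
  # subject offsets are shared across a subject's trials, so use the
  # conservative between-subject standard error
  subj_means <- tapply(proj, fx$sim$records$subject[warm], mean)
  se <- sd(subj_means) / sqrt(length(subj_means))
  expect_lt(abs(mean(proj)), 3 * se)
})

test_that("facial scores show the designed zero inflation and right skew", {
  sim <- get_default_sim()$sim     # default 34 x 16 design
  pain <- sim$records$condition == "pain"
  sc <- facs_scores(sim$records)
  frac0 <- mean(sc$raw[pain] == 0)
  expect_gte(frac0, 0.30)
  expect_lte(frac0, 0.50)
  expect_gt(distribution_stats(sc$raw[pain])["skewness"], 0)
})

test_that("exclusions are flagged per condition and conserve counts", {
  cfg <- tiny_config()
  gt <- make_ground_truth(cfg)
  sim <- simulate_trials(cfg, gt)
  ret <- apply_exclusions(sim$records, cfg)
  summ <- attr(ret, "exclusion_summary")
  expect_equal(summ$retained + summ$excluded, summ$generated)
  expect_equal(sum(ret$condition == "pain"),
               cfg$n_subjects * cfg$trials_per_condition - cfg$n_excluded_pain)
  expect_equal(sum(ret$condition == "warm"),
               cfg$n_subjects * cfg$trials_per_condition - cfg$n_excluded_warm)

  cfg0 <- tiny_config(n_excluded_pain = 0, n_excluded_warm = 0)
  ret0 <- apply_exclusions(sim$records, cfg0)
  expect_equal(nrow(ret0), nrow(sim$records))

  cfg_bad <- tiny_config()
  cfg_bad$n_excluded_pain <- nrow(sim$records)  # more than available
  expect_error(apply_exclusions(sim$records, cfg_bad), "exceeds")
})

test_that("synthetic atlas partitions the mask into contiguous parcels", {
  cfg <- small_config()
  atlas <- make_atlas(cfg, n_networks = 7)
  labs <- atlas$values[atlas$mask]
  expect_setequal(unique(labs), 1:7)
  expect_true(all(atlas$values[!atlas$mask] == 0))
  sizes <- table(labs)
  expect_true(all(sizes >= 0.01 * sum(atlas$mask)))
  # label permutation: relabelling leaves the partition structure intact
  expect_equal(sum(sizes), sum(atlas$mask))
})

test_that("fixture signatures hit their target cosine exactly", {
  cfg <- small_config()
  gt <- make_ground_truth(cfg)
  for (tc in c(-0.5, 0, 0.3, 1)) {
    sig <- make_signature_with_similarity(gt, tc, seed = 3)
    expect_lt(abs(cosine_similarity(sig, gt$true_pattern) - tc), 1e-10)
  }
  expect_error(make_signature_with_similarity(gt, 1.2), "\\[-1, 1\\]")
})

test_that("written study files round-trip key content", {
  cfg <- tiny_config()
  gt <- make_ground_truth(cfg)
  sim <- simulate_trials(cfg, gt)
  dir <- tempfile("study")
  write_study(sim, dir, write_maps = FALSE)
  expect_true(file.exists(file.path(dir, "behavior.tsv")))
  tab <- read.delim(file.path(dir, "behavior.tsv"))
  expect_equal(nrow(tab), nrow(sim$records))
  tp <- read_volume(file.path(dir, "true_pattern.nii.gz"),
                    mask = gt$true_pattern)
  expect_equal(tp$values, gt$true_pattern$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
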