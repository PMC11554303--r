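# Shared desk-scale fixtures, built once per test run.

small_config <- function(seed = 42, ...) {
  generator_config(n_subjects = 10, trials_per_condition = 6,
                   grid_shape = c(14, 16, 14), seed = seed, ...)
}

tiny_config <- function(seed = 7, n_excluded_pain = 2, n_excluded_warm = 1, ...) {
  generator_config(n_subjects = 8, trials_per_condition = 5,
                   grid_shape = c(10, 10, 10),
                   n_excluded_pain = n_excluded_pain,
                   n_excluded_warm = n_excluded_warm, seed = seed, ...)
}

# memoised small simulated study (used by several files)
.fixture_env <- new.env(parent = emptyenv())

# memoised full-scale (default design) simulated study
get_default_sim <- function() {
  if (is.null(.fixture_env$default_sim)) {
    cfg <- generator_config(seed = 9)
    gt <- make_ground_truth(cfg)
    .fixture_env$default_sim <- simulate_trials(cfg, gt)
    .fixture_env$default_cfg <- cfg
  }
  list(sim = .fixture_env$default_sim, cfg = .fixture_env$default_cfg)
}

get_small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- small_config()
    gt <- make_ground_truth(cfg)
    .fixture_env$sim <- simulate_trials(cfg, gt)
    .fixture_env$cfg <- cfg
  }
  list(sim = .fixture_env$sim, cfg = .fixture_env$cfg)
}

# a 1-D volume pair for hand-arithmetic dot-product oracles
line_volume <- function(x, mask = NULL) {
  v <- array(x, c(length(x), 1, 1))
  m <- if (is.null(mask)) NULL else array(mask, c(length(x), 1, 1))
  volume_map(v, mask = m)
}

# independent smooth random map on the same grid/mask as `ref`
random_smooth_map <- function(ref, seed, fwhm_mm = 6) {
  withr::with_seed(seed, {
    raw <- array(stats::rnorm(prod(dim(ref$values))), dim(ref$values))
    sig <- fepsig:::fwhm_to_sigma(fwhm_mm, abs(ref$affine[1, 1]))
    sm <- fepsig:::masked_smooth(raw, ref$mask, rep(sig, 3))
    volume_map(sm, affine = ref$affine, mask = ref$mask, name = "random_map")
  })
}
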