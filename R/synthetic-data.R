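#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the study design the analysis pipeline assumes:
#' 34 participants receiving 16 painful and 16 warm thermal stimulations
#' each, trial-wise activation volumes with a fixed embedded voxel pattern
#' driving a zero-inflated, right-skewed facial-expression score, spatially
#' smooth noise, per-subject random offsets, and a handful of
#' motion-excluded trials per condition.
#'
#' @param n_subjects Number of participants.
#' @param trials_per_condition Trials per condition (pain, warm) per subject,
#'   split evenly over `n_runs` runs.
#' @param n_runs Number of scanning runs.
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param smoothness_fwhm_mm FWHM (mm) of the Gaussian kernel applied to the
#'   embedded pattern and to the noise field; 0 disables smoothing.
#' @param effect_size Coupling strength between the latent trial signal and
#'   the log-mean of the positive part of the facial score. 0 decouples brain
#'   and face.
#' @param signal_amplitude Amplitude of the embedded pattern component in
#'   pain-trial maps (the latent signal multiplies
#'   `signal_amplitude * true_pattern`); sets the imaging signal-to-noise
#'   ratio relative to `noise_sd`.
#' @param latent_mean Mean of the latent pain signal: pain trials load on
#'   the pattern with mean `latent_mean` and unit SD, so a positive value
#'   elevates pain-trial expression over warm trials on average. The facial
#'   coupling acts on the centred deviation, so this shifts the maps without
#'   moving the facial-score distribution.
#' @param subject_sd SD of the per-subject random offset added uniformly to
#'   every in-mask voxel (the imaging analogue of a random intercept).
#' @param noise_sd Voxel-wise SD of the smooth Gaussian noise field.
#' @param zero_inflation_prob Probability that a pain trial shows no facial
#'   response at all (raw composite exactly 0).
#' @param n_excluded_pain,n_excluded_warm Number of trials flagged for
#'   motion exclusion in each condition (drawn uniformly without replacement).
#' @param rating_face_cor Latent correlation between pain ratings and facial
#'   scores within the pain condition; the default 0 reproduces the empirical
#'   independence of ratings and facial responses at constant stimulus
#'   intensity.
#' @param gamma_shape Shape of the Gamma positive part of the facial score.
#' @param raw_log_mean Baseline (latent signal = 0) log-mean of the positive
#'   facial score part.
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 34,
                             trials_per_condition = 16,
                             n_runs = 2,
                             grid_shape = c(20, 24, 20),
                             voxel_size_mm = 3,
                             smoothness_fwhm_mm = 6,
                             effect_size = 1.5,
                             signal_amplitude = 6,
                             latent_mean = 1,
                             subject_sd = 0.5,
                             noise_sd = 1,
                             zero_inflation_prob = 0.4,
                             n_excluded_pain = 11,
                             n_excluded_warm = 8,
                             rating_face_cor = 0,
                             gamma_shape = 2.5,
                             raw_log_mean = 0.7,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    trials_per_condition = as.integer(trials_per_condition),
    n_runs = as.integer(n_runs),
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    smoothness_fwhm_mm = smoothness_fwhm_mm,
    effect_size = effect_size,
    signal_amplitude = signal_amplitude,
    latent_mean = latent_mean,
    subject_sd = subject_sd,
    noise_sd = noise_sd,
    zero_inflation_prob = zero_inflation_prob,
    n_excluded_pain = as.integer(n_excluded_pain),
    n_excluded_warm = as.integer(n_excluded_warm),
    rating_face_cor = rating_face_cor,
    gamma_shape = gamma_shape,
    raw_log_mean = raw_log_mean,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_subjects >= 1, trials_per_condition >= 1, n_runs >= 1,
      length(grid_shape) == 3, all(grid_shape >= 1),
      voxel_size_mm > 0, smoothness_fwhm_mm >= 0,
      effect_size >= 0, signal_amplitude >= 0, is.finite(latent_mean),
      subject_sd >= 0, noise_sd > 0,
      zero_inflation_prob >= 0, zero_inflation_prob <= 1,
      n_excluded_pain >= 0, n_excluded_warm >= 0,
      abs(rating_face_cor) <= 1, gamma_shape > 0
    )
    n_total <- n_subjects * trials_per_condition
    if (n_excluded_pain >= n_total || n_excluded_warm >= n_total)
      stop("exclusion counts must be smaller than the trials per condition",
           call. = FALSE)
  })
  structure(cfg, class = "generator_config")
}

# Ellipsoidal brain mask inscribed in the grid (about pi/6 of the box).
make_brain_mask <- function(grid_shape) {
  d <- grid_shape
  ax <- lapply(1:3, function(k) ((seq_len(d[k]) - (d[k] + 1) / 2) / (d[k] / 2)))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  array(g$x^2 + g$y^2 + g$z^2 <= 1, dim = d)
}

#' Build the generator's ground-truth pattern
#'
#' Places a small set of spherical clusters (two positive, two negative)
#' inside an ellipsoidal brain mask, smooths them with the configured
#' Gaussian kernel, suppresses sub-threshold ringing so the pattern stays
#' sparse, and normalises the result to unit Euclidean norm over the mask.
#' With `smoothness_fwhm_mm = 0` the returned pattern is exactly the
#' unsmoothed cluster stencil (normalised).
#'
#' @param config A [generator_config()].
#' @return A list of class `ground_truth` with elements `true_pattern`
#'   (a [volume_map()]; zero outside the brain mask) and `latent_signal`
#'   (filled in by [simulate_trials()]).
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  d <- config$grid_shape
  if (any(d < 8))
    stop("grid too small to place clusters: need at least 8 voxels per axis",
         call. = FALSE)
  mask <- make_brain_mask(d)

  # cluster centres at fixed relative positions, radii ~2.5 voxels
  centres <- rbind(
    c(0.38, 0.42, 0.52),   # positive
    c(0.64, 0.60, 0.42),   # positive
    c(0.50, 0.34, 0.62),   # negative
    c(0.42, 0.68, 0.40)    # negative
  )
  amps <- c(1, 1, -1, -1)
  radius <- pmax(2, min(d) / 8)

  idx <- which(array(TRUE, d), arr.ind = TRUE)
  stencil <- array(0, d)
  for (k in seq_len(nrow(centres))) {
    ctr <- centres[k, ] * d
    r2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
    stencil[r2 <= radius^2] <- stencil[r2 <= radius^2] + amps[k]
  }
  stencil <- stencil * mask

  sigma <- fwhm_to_sigma(config$smoothness_fwhm_mm, config$voxel_size_mm)
  if (sigma > 0) {
    sm <- masked_smooth(stencil, mask, rep(sigma, 3))
    # keep the pattern sparse: zero out smoothing tails below 5% of the peak
    sm[abs(sm) < 0.05 * max(abs(sm))] <- 0
    pattern <- sm
  } else {
    pattern <- stencil
  }
  nrm <- sqrt(sum(pattern[mask]^2))
  if (nrm == 0) stop("degenerate ground-truth pattern (all zero)", call. = FALSE)
  pattern <- pattern / nrm

  vol <- volume_map(pattern, mask = mask, name = "true_pattern",
                    voxel_size_mm = config$voxel_size_mm)
  structure(list(true_pattern = vol, latent_signal = NULL),
            class = "ground_truth")
}

# Integerise a target raw composite into per-AU frequency and intensity
# counts such that mean(freq) * mean(intensity) is as close as possible to
# the target. Ties are resolved toward smaller totals; occurrences and
# intensity points are dealt to AU4 first.
au_table_grid <- function() {
  out <- NULL
  for (F in 1:40) {
    n_active <- min(F, 4L)
    for (I in n_active:(5L * n_active)) {
      out <- rbind(out, c(F = F, I = I, raw = F * I / 16))
    }
  }
  as.data.frame(out)
}

raw_to_au <- local({
  grid <- NULL
  function(raw) {
    if (is.null(grid)) grid <<- au_table_grid()
    freq <- int <- c(AU4 = 0L, AU67 = 0L, AU910 = 0L, AU43 = 0L)
    if (raw > 0) {
      j <- which.min(abs(grid$raw - raw))
      F <- as.integer(grid$F[j]); I <- as.integer(grid$I[j])
      base <- F %/% 4L
      extra <- F %% 4L
      freq[] <- as.integer(base + (seq_len(4) <= extra))
      active <- which(freq > 0)
      int[active] <- 1L
      left <- I - length(active)
      k <- 1L
      while (left > 0L) {
        a <- active[(k - 1L) %% length(active) + 1L]
        if (int[a] < 5L) { int[a] <- int[a] + 1L; left <- left - 1L }
        k <- k + 1L
      }
    }
    list(freq = freq, int = int)
  }
})

# Hurdle draw of raw facial composites for one vector of latent signals.
draw_facial_raw <- function(z, effect_size, zero_prob, gamma_shape, log_mean) {
  n <- length(z)
  gate <- stats::rbinom(n, 1, 1 - zero_prob)
  mu <- exp(log_mean + effect_size * z)
  pos <- stats::rgamma(n, shape = gamma_shape, scale = mu / gamma_shape)
  gate * pos
}

#' Simulate trial-wise activation maps and behavioral records
#'
#' For every pain trial a latent scalar signal is drawn and the activation
#' volume is `latent * true_pattern + subject offset + smooth noise`; warm
#' trials carry no pattern component. The facial score follows a hurdle
#' model — a Bernoulli gate producing exact zeros, and a Gamma positive part
#' whose log-mean is linear in the latent signal — and is then integerised
#' into per-action-unit frequency and intensity counts so that the composite
#' scoring in the behavior module recovers it up to rounding. Pain ratings
#' are drawn around the moderate-to-strong target range (above the pain
#' threshold at 50/100) with a configurable correlation to the facial score;
#' warm ratings fall below threshold.
#'
#' @param config A [generator_config()].
#' @param gt Output of [make_ground_truth()] on the same config.
#' @return A list of class `simulated_study`: `maps` (a `trial_maps`
#'   container: trials x in-mask-voxel matrix plus grid metadata), `records`
#'   (behavioral data frame, one row per trial), `ground_truth` (with
#'   `latent_signal` filled for pain trials; 0 for warm trials), and
#'   `config`.
#' @export
simulate_trials <- function(config, gt) {
  stopifnot(inherits(config, "generator_config"), inherits(gt, "ground_truth"))
  ref <- gt$true_pattern
  if (!identical(dim(ref$values), as.integer(config$grid_shape)))
    stop("ground truth was generated on a different grid than `config`",
         call. = FALSE)

  withr::with_seed(config$seed, {
    d <- config$grid_shape
    mask <- ref$mask
    n_in <- sum(mask)
    w <- mask_values(ref)
    sigma <- fwhm_to_sigma(config$smoothness_fwhm_mm, config$voxel_size_mm)

    n_sub <- config$n_subjects
    tpc <- config$trials_per_condition
    n_runs <- config$n_runs
    per_run <- diff(round(seq(0, tpc, length.out = n_runs + 1)))

    subj_ids <- sprintf("sub%02d", seq_len(n_sub))
    subj_off <- stats::rnorm(n_sub, 0, config$subject_sd)

    rows <- list()
    for (s in seq_len(n_sub)) {
      for (r in seq_len(n_runs)) {
        conds <- sample(rep(c("pain", "warm"), times = per_run[r]))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj_ids[s], run = r, trial = seq_along(conds),
          condition = conds, stringsAsFactors = FALSE
        )
      }
    }
    rec <- do.call(rbind, rows)
    rec$trial_id <- seq_len(nrow(rec))
    n_trials <- nrow(rec)
    is_pain <- rec$condition == "pain"

    # latent signal: unit-SD normal around latent_mean on pain trials,
    # identically 0 on warm trials
    z <- numeric(n_trials)
    z[is_pain] <- config$latent_mean + stats::rnorm(sum(is_pain))

    # activation maps
    sm_mask <- if (sigma > 0) gaussian_smooth_3d(mask * 1, rep(sigma, 3)) else NULL
    X <- matrix(0, n_trials, n_in)
    for (i in seq_len(n_trials)) {
      noise <- array(stats::rnorm(prod(d)), d)
      if (sigma > 0) noise <- masked_smooth(noise, mask, rep(sigma, 3), den = sm_mask)
      nv <- noise[mask]
      nv <- nv / stats::sd(nv) * config$noise_sd
      s_idx <- match(rec$subject[i], subj_ids)
      X[i, ] <- config$signal_amplitude * z[i] * w + subj_off[s_idx] + nv
    }

    # facial scores: hurdle for pain; warm trials nearly always neutral
    raw <- numeric(n_trials)
    raw[is_pain] <- draw_facial_raw(z[is_pain] - config$latent_mean,
                                    config$effect_size,
                                    config$zero_inflation_prob,
                                    config$gamma_shape, config$raw_log_mean)
    n_warm <- sum(!is_pain)
    raw[!is_pain] <- draw_facial_raw(rep(0, n_warm), 0, 0.95,
                                     config$gamma_shape,
                                     config$raw_log_mean - 1.5)

    au <- lapply(raw, raw_to_au)
    rec$AU4_freq   <- vapply(au, function(a) a$freq[["AU4"]], integer(1))
    rec$AU4_int    <- vapply(au, function(a) a$int[["AU4"]], integer(1))
    rec$AU67_freq  <- vapply(au, function(a) a$freq[["AU67"]], integer(1))
    rec$AU67_int   <- vapply(au, function(a) a$int[["AU67"]], integer(1))
    rec$AU910_freq <- vapply(au, function(a) a$freq[["AU910"]], integer(1))
    rec$AU910_int  <- vapply(au, function(a) a$int[["AU910"]], integer(1))
    rec$AU43_freq  <- vapply(au, function(a) a$freq[["AU43"]], integer(1))
    rec$AU43_int   <- vapply(au, function(a) a$int[["AU43"]], integer(1))

    # pain ratings: moderate-to-strong above the 50/100 pain threshold,
    # correlated with the (log-scale) facial score only if requested
    rho <- config$rating_face_cor
    face_z <- as.numeric(scale(log1p(raw[is_pain])))
    if (all(!is.finite(face_z))) face_z <- rep(0, sum(is_pain))
    rate_noise <- stats::rnorm(sum(is_pain))
    rating <- numeric(n_trials)
    rating[is_pain] <- pmin(100, pmax(
      50, 77 + 8 * (rho * face_z + sqrt(max(0, 1 - rho^2)) * rate_noise)))
    rating[!is_pain] <- pmin(49, pmax(0, stats::rnorm(n_warm, 20, 10)))
    rec$rating <- rating
    rec$excluded <- FALSE

    maps <- structure(
      list(data = X, ref = ref, trial_id = rec$trial_id),
      class = "trial_maps"
    )
    gt$latent_signal <- z
    structure(
      list(maps = maps, records = rec, ground_truth = gt, config = config),
      class = "simulated_study"
    )
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d subjects, %d trials (%d pain / %d warm), %d in-mask voxels\n",
              x$config$n_subjects, nrow(x$records),
              sum(x$records$condition == "pain"),
              sum(x$records$condition == "warm"),
              sum(x$maps$ref$mask)))
  invisible(x)
}

#' Extract one trial's activation volume
#'
#' @param maps A `trial_maps` container (from [simulate_trials()]).
#' @param i Row index into the container.
#' @return A [volume_map()].
#' @export
trial_volume <- function(maps, i) {
  stopifnot(inherits(maps, "trial_maps"))
  embed_values(maps$data[i, ], maps$ref, name = sprintf("trial%04d", maps$trial_id[i]))
}

#' Flag motion exclusions and return the retained trials
#'
#' Chooses `n_excluded_pain` pain trials and `n_excluded_warm` warm trials
#' uniformly at random (seeded from the config), flags them, and returns the
#' retained set.
#'
#' @param records Behavioral data frame from [simulate_trials()].
#' @param config The [generator_config()] used to simulate.
#' @return The retained records (rows with `excluded = FALSE`), with an
#'   attribute `exclusion_summary` giving generated / excluded / retained
#'   counts per condition.
#' @export
apply_exclusions <- function(records, config) {
  stopifnot(inherits(config, "generator_config"))
  pain_idx <- which(records$condition == "pain")
  warm_idx <- which(records$condition == "warm")
  if (config$n_excluded_pain > length(pain_idx) ||
      config$n_excluded_warm > length(warm_idx))
    stop("exclusion count exceeds available trials in a condition", call. = FALSE)
  excl <- withr::with_seed(config$seed + 1L, {
    c(
      if (config$n_excluded_pain > 0)
        sample(pain_idx, config$n_excluded_pain) else integer(0),
      if (config$n_excluded_warm > 0)
        sample(warm_idx, config$n_excluded_warm) else integer(0)
    )
  })
  records$excluded <- seq_len(nrow(records)) %in% excl
  retained <- records[!records$excluded, , drop = FALSE]
  summary <- data.frame(
    condition = c("pain", "warm"),
    generated = c(length(pain_idx), length(warm_idx)),
    excluded = c(config$n_excluded_pain, config$n_excluded_warm),
    retained = c(length(pain_idx) - config$n_excluded_pain,
                 length(warm_idx) - config$n_excluded_warm)
  )
  attr(retained, "exclusion_summary") <- summary
  retained
}

#' Build a synthetic network atlas
#'
#' Partitions the in-mask voxels into `n_networks` contiguous parcels by
#' k-means on voxel world coordinates (the Voronoi cells of the fitted
#' centres, which are contiguous on a convex mask). Label 0 is background;
#' labels are renumbered by centre position so the parcellation is stable.
#' The fixture plays the role a cortical network parcellation (e.g. a
#' seven-network atlas) plays for real signature maps.
#'
#' @param config A [generator_config()].
#' @param n_networks Number of parcels (>= 2).
#' @return An integer-valued [volume_map()] with labels 0..n_networks.
#' @export
make_atlas <- function(config, n_networks = 7) {
  stopifnot(inherits(config, "generator_config"), n_networks >= 2)
  mask <- make_brain_mask(config$grid_shape)
  ref <- volume_map(array(0, config$grid_shape), mask = mask,
                    voxel_size_mm = config$voxel_size_mm, name = "atlas")
  xyz <- mask_coords_mm(ref)
  km <- withr::with_seed(config$seed + 2L,
                         stats::kmeans(xyz, centers = n_networks, nstart = 5,
                                       iter.max = 50))
  ord <- order(km$centers[, 1], km$centers[, 2], km$centers[, 3])
  relabel <- match(seq_len(n_networks), ord)
  lab <- relabel[km$cluster]
  vals <- array(0, config$grid_shape)
  vals[mask] <- lab
  volume_map(vals, affine = ref$affine, mask = mask,
             voxel_size_mm = config$voxel_size_mm, name = "atlas")
}

#' Construct a signature map with a prescribed cosine to the true pattern
#'
#' Returns `cos(theta) * u_hat + sin(theta) * v_hat` where `u_hat` is the
#' unit-norm true pattern and `v_hat` a random (spatially smoothed) unit
#' vector orthogonalised against it, so that the in-mask cosine similarity
#' with the true pattern equals `target_cosine` to numerical precision.
#' Used as a stand-in for external comparison signatures.
#'
#' @param gt Output of [make_ground_truth()].
#' @param target_cosine Desired cosine in `[-1, 1]`.
#' @param seed Integer seed for the random direction.
#' @param smooth_fwhm_mm FWHM of smoothing applied to the random direction
#'   before orthogonalisation, giving the fixture realistic spatial
#'   autocorrelation.
#' @return A [volume_map()].
#' @export
make_signature_with_similarity <- function(gt, target_cosine, seed = 1L,
                                           smooth_fwhm_mm = 6) {
  stopifnot(inherits(gt, "ground_truth"))
  if (abs(target_cosine) > 1)
    stop("`target_cosine` must lie in [-1, 1]", call. = FALSE)
  ref <- gt$true_pattern
  u <- mask_values(ref)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("true pattern has zero norm", call. = FALSE)
  u_hat <- u / nu
  if (abs(target_cosine) == 1)
    return(embed_values(target_cosine * u_hat, ref, name = "fixture_signature"))
  v <- withr::with_seed(seed, {
    raw <- array(stats::rnorm(prod(dim(ref$values))), dim(ref$values))
    sig <- fwhm_to_sigma(smooth_fwhm_mm, abs(ref$affine[1, 1]))
    if (sig > 0) raw <- masked_smooth(raw, ref$mask, rep(sig, 3))
    raw[ref$mask]
  })
  v <- v - sum(v * u_hat) * u_hat
  v_hat <- v / sqrt(sum(v^2))
  theta <- acos(target_cosine)
  s <- cos(theta) * u_hat + sin(theta) * v_hat
  embed_values(s, ref, name = "fixture_signature")
}

#' Write a simulated study to disk
#'
#' Volumes go out as NIfTI (`.nii.gz`), the behavioral table as TSV, the
#' ground-truth pattern as NIfTI plus a JSON manifest of the configuration.
#'
#' @param sim A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @param write_maps Write one NIfTI per trial (can be slow for full-size
#'   simulations); the mask and ground truth are always written.
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir, write_maps = TRUE) {
  stopifnot(inherits(sim, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- sim$maps$ref
  write_volume(volume_map(array(as.numeric(ref$mask), dim(ref$values)),
                          affine = ref$affine, mask = ref$mask, name = "mask"),
               file.path(dir, "mask.nii.gz"))
  write_volume(sim$ground_truth$true_pattern,
               file.path(dir, "true_pattern.nii.gz"))
  utils::write.table(sim$records, file.path(dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (write_maps) {
    map_dir <- file.path(dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(sim$maps$data))) {
      write_volume(trial_volume(sim$maps, i),
                   file.path(map_dir, sprintf("trial%04d.nii.gz",
                                              sim$maps$trial_id[i])))
    }
  }
  manifest <- unclass(sim$config)
  manifest$latent_signal <- sim$ground_truth$latent_signal
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
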