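#' Pipeline analysis settings
#'
#' Replicate counts and model settings for an end-to-end run. Desk-scale
#' defaults keep a full run in minutes; `paper_scale = TRUE` switches the
#' resampling counts to the full 5000 permutations / 5000 bootstrap samples
#' / 1000 surrogate maps used for production inference.
#'
#' @param k Cross-validation folds.
#' @param penalty LASSO penalty weight.
#' @param n_perm Permutation iterations.
#' @param n_boot Bootstrap resamples.
#' @param n_null Surrogate maps for similarity tests.
#' @param fdr_q FDR level for the thresholded weight map.
#' @param n_networks Parcels in the synthetic atlas.
#' @param write_maps Write per-trial NIfTI volumes to disk.
#' @param paper_scale Use production replicate counts.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(k = 10, penalty = 1, n_perm = 200, n_boot = 200,
                            n_null = 199, fdr_q = 0.05, n_networks = 7,
                            write_maps = FALSE, paper_scale = FALSE) {
  if (paper_scale) {
    n_perm <- 5000; n_boot <- 5000; n_null <- 1000
  }
  structure(list(k = k, penalty = penalty, n_perm = n_perm, n_boot = n_boot,
                 n_null = n_null, fdr_q = fdr_q, n_networks = n_networks,
                 write_maps = write_maps, paper_scale = paper_scale),
            class = "analysis_config")
}

#' Read a pipeline configuration file
#'
#' Accepts YAML or JSON with two optional blocks, `generator` and
#' `analysis`, whose fields override the defaults of [generator_config()]
#' and [analysis_config()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return List with elements `generator` and `analysis`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  gen <- do.call(generator_config, as.list(raw$generator))
  ana <- do.call(analysis_config, as.list(raw$analysis))
  list(generator = gen, analysis = ana)
}

stage_hashes <- function(paths) {
  paths <- paths[file.exists(paths) & basename(paths) != "manifest.json"]
  as.list(tools::md5sum(paths))
}

#' Run the full analysis pipeline
#'
#' Executes the six stages end to end on synthetic data: simulate (volumes,
#' behavior, exclusions), behavioral scoring and QC, signature training
#' (grouped cross-validation, permutation test, bootstrap weight inference
#' with FDR thresholding), condition contrasts on expression scores,
#' spatial-similarity analysis against fixture signatures, and report
#' writing. Each stage's outputs are inputs to the next; any stage failure
#' halts the run with the stage recorded in the manifest.
#'
#' @param generator A [generator_config()] (or path to a config file read
#'   with [read_pipeline_config()], in which case `analysis` is ignored).
#' @param analysis An [analysis_config()].
#' @param out_dir Output directory.
#' @return A list of class `run_manifest`: configuration snapshot, per-stage
#'   status, output paths with MD5 hashes, and the key result tables.
#' @export
run_pipeline <- function(generator = generator_config(),
                         analysis = analysis_config(),
                         out_dir) {
  if (is.character(generator)) {
    cfg <- read_pipeline_config(generator)
    generator <- cfg$generator
    analysis <- cfg$analysis
  }
  stopifnot(inherits(generator, "generator_config"),
            inherits(analysis, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fepsig")),
    generator = unclass(generator),
    analysis = unclass(analysis),
    stages = list(),
    outputs = list()
  )
  results <- list()
  t_all <- Sys.time()

  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    message(sprintf("[%s] stage %-12s seed=%d", format(Sys.time(), "%H:%M:%S"),
                    name, generator$seed))
    out <- tryCatch(fn(), error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(out, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(out),
                                       seconds = elapsed)
      manifest_path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA, force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(out)), call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "completed", seconds = elapsed)
    out
  }

  # 1 -- simulate
  sim_out <- run_stage("simulate", function() {
    gt <- make_ground_truth(generator)
    sim <- simulate_trials(generator, gt)
    retained <- apply_exclusions(sim$records, generator)
    sim$records$excluded <- !(sim$records$trial_id %in% retained$trial_id)
    write_study(sim, file.path(out_dir, "data"),
                write_maps = analysis$write_maps)
    list(sim = sim, retained = retained)
  })
  sim <- sim_out$sim
  retained <- sim_out$retained
  results$exclusions <- attr(retained, "exclusion_summary")

  # 2 -- behavior
  behav <- run_stage("behavior", function() {
    sc <- facs_scores(sim$records)
    pain_ret <- retained[retained$condition == "pain", ]
    sc_pain <- sc[match(pain_ret$trial_id, sc$trial_id), ]
    dist <- distribution_stats(sc_pain$transformed)
    qc_rate <- qc_rating_association(sc_pain$transformed, pain_ret$rating,
                                     pain_ret$subject)
    qc_hab <- qc_habituation(sc_pain$transformed, pain_ret$trial,
                             pain_ret$run, pain_ret$subject)
    utils::write.table(sc, file.path(out_dir, "facs_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(distribution = as.list(dist),
           rating_association = qc_rate$fixed_effects,
           rating_association_r2 = c(marginal = qc_rate$marginal_r2,
                                     conditional = qc_rate$conditional_r2),
           habituation = qc_hab$fixed_effects),
      file.path(out_dir, "behavior_qc.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    list(scores = sc, dist = dist, qc_rate = qc_rate, qc_hab = qc_hab)
  })
  results$facs_distribution <- behav$dist

  # 3 -- train
  train <- run_stage("train", function() {
    ds <- build_dataset(sim$maps, behav$scores, retained)
    cv <- cross_validate(ds, k = analysis$k, penalty = analysis$penalty,
                         seed = generator$seed)
    perm <- permutation_test(ds, k = analysis$k, penalty = analysis$penalty,
                             n_perm = analysis$n_perm, seed = generator$seed)
    boot <- bootstrap_weights(ds, penalty = analysis$penalty,
                              n_boot = analysis$n_boot, seed = generator$seed)
    thr <- threshold_fdr(boot$p_map, q = analysis$fdr_q)
    model <- fit_lasso_pcr(ds, penalty = analysis$penalty)
    write_volume(model$weight_map, file.path(out_dir, "signature_weights.nii.gz"))
    write_volume(boot$z_map, file.path(out_dir, "bootstrap_z.nii.gz"))
    write_volume(boot$p_map, file.path(out_dir, "bootstrap_p.nii.gz"))
    write_volume(thr, file.path(out_dir, "signature_fdr_mask.nii.gz"))
    jsonlite::write_json(
      list(cv_per_fold = cv$per_fold, cv_summary = cv$summary,
           folds = cv$folds,
           permutation = list(observed = perm$observed, p = perm$p,
                              statistic = perm$statistic,
                              n_perm = perm$n_perm),
           bootstrap = list(n_boot = boot$n_boot,
                            n_flagged = boot$n_flagged,
                            n_fdr_voxels = sum(mask_values(thr) > 0)),
           n_components = model$n_components_retained,
           n_nonzero_components = model$n_nonzero_components),
      file.path(out_dir, "training_metrics.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(data.frame(null = perm$null_scores),
                       file.path(out_dir, "permutation_null.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(ds = ds, cv = cv, perm = perm, boot = boot, thr = thr, model = model)
  })
  results$cv_summary <- train$cv$summary
  results$permutation_p <- train$perm$p

  # 4 -- contrast
  contrast <- run_stage("contrast", function() {
    expr <- expression_scores(sim$maps, train$model$weight_map)
    ret_expr <- expr[match(retained$trial_id, expr$trial_id), ]
    sc_ret <- behav$scores[match(retained$trial_id, behav$scores$trial_id), ]
    strata <- stratify_pain_by_facs(retained$condition, sc_ret$raw)
    cc <- condition_contrast(ret_expr$score, strata, retained$subject)
    pain_sel <- retained$condition == "pain"
    assoc <- correlate_expression(ret_expr$score[pain_sel],
                                  sc_ret$transformed[pain_sel])
    qc <- qc_feps_vs_ratings(sc_ret$transformed[pain_sel],
                             ret_expr$score[pain_sel],
                             retained$rating[pain_sel],
                             retained$subject[pain_sel])
    utils::write.table(cbind(retained[, c("trial_id", "subject", "condition")],
                             score = ret_expr$score),
                       file.path(out_dir, "expression_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(contrasts = cc$contrasts, emmeans = cc$emmeans,
           pain_association = assoc[c("r", "p", "ci", "n")],
           feps_vs_ratings = qc$fixed_effects),
      file.path(out_dir, "contrasts.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    list(cc = cc, assoc = assoc, qc = qc)
  })
  results$contrasts <- contrast$cc$contrasts
  results$pain_association <- contrast$assoc

  # 5 -- similarity
  sim_stage <- run_stage("similarity", function() {
    atlas <- make_atlas(generator, n_networks = analysis$n_networks)
    fixtures <- list(
      cos_0.5 = make_signature_with_similarity(sim$ground_truth, 0.5,
                                               seed = generator$seed + 10L),
      cos_0.0 = make_signature_with_similarity(sim$ground_truth, 0.0,
                                               seed = generator$seed + 11L)
    )
    w <- train$model$weight_map
    rows <- lapply(names(fixtures), function(nm) {
      sp <- similarity_pvalue(w, fixtures[[nm]], atlas = atlas,
                              n = analysis$n_null,
                              seed = generator$seed + 12L)
      nets <- vapply(sp$networks, `[[`, numeric(1), "observed")
      data.frame(comparison = nm,
                 scope = c("whole_brain", names(sp$networks)),
                 observed = c(sp$whole_brain$observed, nets),
                 p = c(sp$whole_brain$p,
                       vapply(sp$networks, `[[`, numeric(1), "p")))
    })
    tab <- do.call(rbind, rows)
    tab$scope <- sub("^([0-9])", "network:\\1", tab$scope)
    utils::write.csv(tab, file.path(out_dir, "similarity.csv"),
                     row.names = FALSE)
    write_volume(atlas, file.path(out_dir, "atlas.nii.gz"))
    list(table = tab, truth_cosine = cosine_similarity(
      w, sim$ground_truth$true_pattern))
  })
  results$similarity <- sim_stage$table
  results$truth_cosine <- sim_stage$truth_cosine

  # 6 -- report
  run_stage("report", function() {
    rp <- file.path(out_dir, "report.md")
    con <- file(rp, "w")
    on.exit(close(con))
    wl <- function(...) writeLines(sprintf(...), con)
    wl("# Pipeline report")
    wl("")
    wl("## Trial bookkeeping")
    ex <- results$exclusions
    for (i in seq_len(nrow(ex)))
      wl("- %s: %d generated, %d excluded, %d retained",
         ex$condition[i], ex$generated[i], ex$excluded[i], ex$retained[i])
    wl("")
    wl("## Cross-validated decoding")
    cs <- results$cv_summary
    for (i in seq_len(nrow(cs)))
      wl("- %s: %.3f +/- %.3f", cs$metric[i], cs$mean[i], cs$sd[i])
    wl("- permutation p = %.4g", results$permutation_p)
    wl("- cosine(fitted weights, true pattern) = %.3f", results$truth_cosine)
    wl("")
    wl("## Condition contrasts (expression scores)")
    cc <- results$contrasts
    for (i in seq_len(nrow(cc)))
      wl("- %s: EMM diff %.3f +/- %.3f, t(%.0f) = %.2f, p = %.3g, d = %.2f",
         cc$contrast[i], cc$emm_difference[i], cc$se[i], cc$df[i],
         cc$t[i], cc$p[i], cc$cohens_d[i])
    wl("")
    wl("## Spatial similarity (fitted signature vs fixtures)")
    st <- results$similarity
    for (i in seq_len(nrow(st)))
      wl("- %s / %s: cosine %.3f, p = %.3g", st$comparison[i], st$scope[i],
         st$observed[i], st$p[i])
    invisible(NULL)
  })

  manifest$outputs <- stage_hashes(list.files(out_dir, recursive = TRUE,
                                              full.names = TRUE))
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all,
                                                units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(c(manifest, list(results = results)), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s (%.1fs)\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$seconds))
  invisible(x)
}
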