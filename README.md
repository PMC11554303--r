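# fepsig

Training and evaluating brain signatures of the facial expression of pain.

## The problem

During painful stimulation people communicate pain through two partly
independent channels: the rating they report and the expression on their
face. `fepsig` implements an end-to-end, fully tested pipeline for
developing a multivariate brain signature of the *facial* channel from
trial-wise fMRI activation maps:

* **Behavioral scoring** — the FACS composite outcome
  (mean action-unit frequency × mean action-unit intensity over AU4,
  AU6-7, AU9-10, AU43), its `ln(1 + x)` transform, distribution
  diagnostics, and mixed-model quality controls (rating association,
  habituation/sensitization).
* **Signature training** — LASSO principal-component regression
  (all SVD components retained, L1 penalty fixed at 1.0 on
  unstandardised component scores), validated by participant-grouped
  10-fold cross-validation (Pearson r, R² = 1 − SS_res/SS_tot on the test
  fold, RMSE), with permutation tests on cross-validated performance,
  bootstrap z-maps on voxel weights (`z = mean/SD` over resamples),
  Benjamini–Hochberg FDR thresholding, ROI-restricted models, and the
  corrected resampled t-test `t = mean(d)/sqrt((1/J + n_test/n_train)·s²_d)`
  for model comparison.
* **Pattern expression** — dot-product expression scores of any map
  against any signature, correlations with behavior (Fisher-z CIs), and
  pain/warm condition contrasts on estimated marginal means with Tukey
  adjustment and standardised effect sizes.
* **Spatial similarity** — whole-brain and network-wise cosine similarity
  between weight maps, with significance from variogram-matched surrogate
  maps that preserve spatial autocorrelation (two-sided-by-absolute-value
  p with the add-one convention).
* **Synthetic data** — a first-class generator emulating the study
  design (34 participants × 16 trials per condition, 544 trials per
  condition, 11/8 motion exclusions → 533/536 retained maps) with a known
  embedded pattern, a zero-inflated right-skewed facial outcome, smooth
  noise and subject random effects, so the entire pipeline is testable
  without access to participant data.

See the methods vignette
(`vignettes/decoding-facial-pain-expression.Rmd`) for the model, its
assumptions, all tunable parameters, and known limitations.

## Worked example

```r
library(fepsig)

# simulate the default study design with a known embedded pattern
cfg <- generator_config(seed = 9)
gt  <- make_ground_truth(cfg)
sim <- simulate_trials(cfg, gt)
retained <- apply_exclusions(sim$records, cfg)
attr(retained, "exclusion_summary")
#>   condition generated excluded retained
#> 1      pain       544       11      533
#> 2      warm       544        8      536

# behavioral outcome and training dataset (retained pain trials)
scores <- facs_scores(sim$records)
ds <- build_dataset(sim$maps, scores, retained)
ds
#> <training_dataset> 533 trials x 5032 voxels, 34 subjects

# participant-grouped 10-fold cross-validation of LASSO-PCR
cv <- cross_validate(ds, k = 10, penalty = 1, seed = 9)
cv
#> <cv_result> 10 folds
#>   metric  mean     sd
#> 1      r 0.429 0.1319
#> 2     r2 0.115 0.0806
#> 3   rmse 0.866 0.1449

# the fitted signature recovers the generator's embedded pattern
model <- fit_lasso_pcr(ds, penalty = 1)
cosine_similarity(model$weight_map, gt$true_pattern)
#> [1] 0.871
```

The cross-validated r of about 0.43 says the signature predicts the facial
score of trials from *unseen participants* well above chance at the
generator's moderate signal-to-noise; the cosine of ~0.87 says the voxel
weights point in nearly the same direction as the true embedded pattern.
A permutation test (`permutation_test(ds, ...)`) formalises the
above-chance claim, and `bootstrap_weights()` + `threshold_fdr()` yield
the thresholded weight map. `run_pipeline()` chains all six stages
(simulate → behavior → train → contrast → similarity → report) under one
config and writes a Markdown report plus a manifest with content hashes;
`inst/cli/feps-run.R` is a thin command-line wrapper around it.

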