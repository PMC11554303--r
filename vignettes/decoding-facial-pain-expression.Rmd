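---
title: "Decoding the facial expression of pain from trial-wise brain maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the facial expression of pain from trial-wise brain maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Facial expression is a spontaneous, partially involuntary channel of pain
communication, distinct from the deliberate self-report captured by a
rating scale. `fepsig` implements a complete analysis chain for asking
whether a distributed brain activity pattern measured during noxious heat
predicts how strongly a person's face expresses pain on that trial, and for
characterising the resulting voxel-weight *signature*: how well it decodes
out-of-sample people, which voxels drive it, how it responds to innocuous
warm stimulation, and how spatially similar it is to other published
pain-related signatures.

The package operates on three kinds of objects:

* trial-wise activation (beta) volumes with a brain mask (`volume_map`,
  NIfTI in/out via RNifti);
* a behavioral table with per-trial action-unit (AU) frequency and
  intensity codes, pain ratings on a 0-100 scale (50 = pain threshold),
  and motion-exclusion flags;
* signature weight maps and an integer-labelled network atlas for the
  similarity analyses.

Because the participant-level data this kind of study rests on are
typically not shareable, the package ships a first-class synthetic-data
generator that emulates the study design — 34 participants, 16 pain and 16
warm trials each (544 per condition), 11 pain / 8 warm motion exclusions
(533 and 536 retained maps) — with a *known* embedded pattern, so every
stage of the pipeline can be validated against ground truth.

## The behavioral outcome

Certified FACS coding yields, per trial, the frequency and 5-point
intensity of four pain-related action units (AU4 brow lowering, AU6-7
orbit tightening, AU9-10 levator contraction, AU43 eye closure). The
composite outcome is

$$\mathrm{FACS} = \overline{\mathrm{freq}} \times \overline{\mathrm{int}},$$

the product of the mean AU frequency and mean AU intensity
(`compute_facs_composite()`). Means are taken over all four AU categories
including zeros: the categories are a fixed taxonomy, and including
inactive AUs keeps the composite bounded and monotone in every component.
The modelled score is `ln(FACS + 1)`, which maps "no facial response" to
exactly 0 and tames the strong right skew of the raw composite. The
natural logarithm is used; downstream inference is invariant to the base
up to a scale factor on coefficients. `distribution_stats()` reports
moment (population) skewness and *excess* kurtosis — the only convention
under which a unimodal right-skewed score can legitimately show negative
kurtosis, as such data do.

Two quality-control mixed models accompany the outcome
(`qc_rating_association()`, `qc_habituation()`): FACS as a function of the
pain rating (random intercepts and rating slopes per participant), and
FACS as a function of trial, run and their interaction (random
intercepts). Both are REML fits with Satterthwaite degrees of freedom;
marginal and conditional R² follow the Nakagawa–Schielzeth variance
decomposition with Johnson's extension for random slopes, computed
in-package. When a random-slope fit is singular the model falls back to
random intercepts only and flags the result rather than reporting
coefficients from a degenerate covariance fit.

## The signature model

`fit_lasso_pcr()` implements LASSO principal-component regression:

1. voxel columns are centred by their training means;
2. the centred matrix is decomposed by SVD and **all** components with
   nonzero singular value are retained (at most n − 1) — shrinkage is
   delegated entirely to the L1 penalty, matching the canonical LASSO-PCR
   formulation, which specifies no component cutoff;
3. an L1-penalised regression with fixed penalty weight (default 1.0) is
   fit on the *unstandardised* component scores with an intercept (the
   glmnet objective `(1/2n)||y − b0 − Sb||² + λ||b||₁` at the single fixed
   λ). Scores and outcome are deliberately not rescaled: the penalty is
   specified as an absolute weight, and its effective shrinkage therefore
   depends on data scale, which the model records;
4. component coefficients are back-projected to voxel space, giving the
   prediction rule `ŷ(x) = (x − column_means)·w + intercept`.

A penalty beyond the path maximum yields a valid constant predictor (the
training mean) with a warning, not an error.

Validation is by participant-grouped k-fold cross-validation
(`cross_validate()`, default k = 10): subjects are shuffled by seed and
dealt round-robin into folds, so no participant contributes to both sides
of a split. Per fold the package reports Pearson r, the coefficient of
determination `1 − SS_res/SS_tot` evaluated on the test fold (negative
when the model underperforms the test-fold mean — negative values are
informative and are not clipped), and RMSE.

Inference on performance uses a permutation test
(`permutation_test()`): the outcome is permuted across *all* trials and
the complete grouped cross-validation is re-run per iteration; the
p-value uses the add-one convention `(b + 1)/(n + 1)`, which cannot be
zero and is valid at any replicate count. Inference on voxel weights uses
a bootstrap (`bootstrap_weights()`): trials are resampled with replacement
to the original size, the model is refit on each resample, and each
voxel's `z = mean/SD` over resamples is converted to a two-sided normal
p-value, thresholded by Benjamini–Hochberg FDR (`threshold_fdr()`).
Resampling the trial (not the participant) is the default because the
procedure is defined on "the same number of observations"; a
subject-level bootstrap is available behind `unit = "subject"`. Voxels
with zero bootstrap SD are flagged and assigned p = 1 rather than an
infinite z.

Two models (e.g. whole-brain versus a motor-cortex-restricted mask built
with `restrict_to_roi()`) are compared with the corrected resampled
t-test (`corrected_resampled_ttest()`): fold differences with variance
inflated by `1/J + n_test/n_train` to account for overlapping training
sets, df = J − 1.

### Computational note

Cross-validation, permutation and bootstrap all refit the same matrix on
row subsets. Every such subset lives in the row space of the full data, so
the package expresses all rows once in the basis of the full data's right
singular vectors and refits in that n-dimensional coordinate space,
back-projecting voxel weights at the end. This is exact linear algebra
(tested against direct voxel-space refits to 1e-6), not an approximation,
and it makes 200-fold resampling loops tractable on one CPU.

## Expression scoring and condition contrasts

The expression of a signature in a new map is the dot product over the
voxels common to both masks (`compute_expression()`); missing voxels
contribute nothing. Expression is linear in the activation map, which the
test suite checks to 1e-10. Correlations between expression scores and
behavior report two-sided p-values with 95% confidence intervals by the
Fisher z-transform, `tanh(atanh r ± 1.96/√(n−3))` — the interval method
for such correlations is otherwise underdetermined, and Fisher z is the
default choice.

`condition_contrast()` fits `score ~ condition` with random intercepts per
participant and compares conditions via all pairwise contrasts on the
estimated marginal means with Tukey adjustment. Pain trials can be
stratified by whether any facial response occurred
(`stratify_pain_by_facs()`), giving the three-level contrast
(warm, pain without expression, pain with expression). The standardised
effect size divides the EMM difference by the square root of the summed
random-effect and residual variances (a "total SD" convention, stated
here because d alongside mixed-model contrasts is not otherwise
well-defined); the classical pooled-SD two-sample `cohens_d()` is also
provided.

## Spatial similarity with autocorrelation-preserving nulls

Whole-brain and network-wise similarity between weight maps is cosine
similarity (`cosine_similarity()`, `network_similarity()`). Significance
testing must respect spatial autocorrelation: a naive permutation of
voxels produces far too liberal p-values for smooth maps. The package
generates variogram-matched surrogates (`generate_surrogates()`): each
surrogate is a random permutation of the comparison map's values, smoothed
with the best Gaussian kernel from a candidate ladder (defaults: 0.75 to 8
voxel widths), mixed with white noise so its empirical variogram matches
the target's by least squares over distance bins, and rescaled to the
target's exact in-mask mean and SD. Variograms are estimated on a seeded
subsample of voxel pairs (25 bins covering the short-range quarter of the
mask diameter, at most 5000 pairs per bin by default) because all-pairs
variograms are quadratic in voxel count. The fit is weighted by per-bin
pair counts and deliberately restricted to short range: long-distance bins
hover around the sill and carry almost no information about the
autocorrelation structure that governs the null width, and letting them
dominate the least-squares fit measurably under-disperses the surrogate
null. The same pair sample is reused for the target and all its surrogates
so that the match criterion is directly comparable.

`similarity_pvalue()` surrogates the *comparison* map while the reference
map stays fixed, making the null hypothesis "a random map with the
comparison map's smoothness". P-values are two-sided by absolute value
with the add-one convention. Per-network p-values are reported without
cross-network multiplicity correction by default (matching per-network
reporting conventions); `adjust = "BH"` applies a correction.

A constant map yields constant surrogates by construction. Fixture
signatures with an exact prescribed cosine against the generator's true
pattern are built by `make_signature_with_similarity()` (a rotation in the
plane spanned by the pattern and a random orthogonalised direction), and
round-trip to the target cosine within 1e-10.

## What the generator emulates — and what it does not

`generator_config()` defaults define the emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 34 | participants |
| `trials_per_condition` | 16 | pain and warm trials per subject (8 per run, 2 runs) |
| `n_excluded_pain` / `n_excluded_warm` | 11 / 8 | motion exclusions, drawn uniformly |
| `grid_shape`, `voxel_size_mm` | 20x24x20, 3 mm | desk-scale grid, ~5000 in-mask voxels |
| `smoothness_fwhm_mm` | 6 | Gaussian smoothness of pattern and noise |
| `zero_inflation_prob` | 0.4 | pain trials with no facial response |
| `effect_size` | 1.5 | latent-signal coupling to the facial score |
| `signal_amplitude` | 6 | pattern amplitude in the maps, relative to `noise_sd` = 1 |
| `subject_sd` | 0.5 | per-subject offset SD |

Pain-trial maps are `signal_amplitude · z · w* + subject offset + smooth
noise` with `z ~ N(0,1)` latent per trial and `w*` a sparse unit-norm
pattern of two positive and two negative smoothed clusters inside an
ellipsoidal mask. Warm maps carry no pattern component. The facial score
follows a hurdle model: a Bernoulli gate produces exact zeros with
probability 0.4, and the positive part is Gamma with log-mean linear in
`z` — reproducing the zero mass and right skew that motivate the
log transform. The raw score is then integerised into per-AU frequency
and intensity counts (occurrences dealt to AU4 first) so that composite
scoring recovers it up to rounding, keeping the behavior module
exercisable end-to-end. Pain ratings are drawn in the moderate-to-strong
range above the 50/100 threshold with zero correlation to the facial
score by default, emulating the empirical independence of ratings and
facial responses at constant stimulus intensity; warm ratings fall below
threshold. Warm-trial facial scores use a high-zero-probability (0.95),
low-mean hurdle draw, purely so the stratified contrasts have realistic
warm-condition behavior.

Noise smoothness uses white Gaussian noise convolved with the configured
FWHM and rescaled — matching the smoothness a preprocessing pipeline
induces without modelling scanner physics. The default `signal_amplitude`
and `effect_size` were chosen once to place the default design at
*moderate* signal-to-noise — cross-validated r around 0.5 and
truth-pattern cosine around 0.85 — i.e. a regime where decoding succeeds
but is far from ceiling, comparable to realistic decoding performance.

The generator does **not** emulate: hemodynamic time courses or
first-level GLM estimation (it produces beta-like maps directly),
realistic motion artifacts (exclusions are uniform draws), anatomical
structure (the mask is an ellipsoid, the atlas a k-means parcellation),
inter-coder disagreement in FACS scoring, or heavy-tailed/structured
noise. Passing tests on synthetic data therefore demonstrate the
*correctness and calibration of the statistical machinery* — recovery of
an embedded pattern at its designed SNR, type-I control of permutation
and surrogate tests — not that real data contain such a signal.

## Numerical choices and degenerate inputs

* Alignment of two volumes requires equal shapes and affines within
  1e-4 mm; misaligned inputs error rather than silently resample.
  Nearest-neighbour resampling is the only supported interpolation for
  weight maps (interpolation would smooth weights), and must be requested
  explicitly.
* SVD components are retained above `max(dim) · eps · d1`; ranks are never
  padded.
* The single-component edge case of the L1 fit is solved in closed form
  (soft thresholding) since the path solver requires two columns.
* Zero-variance predictions in a CV fold yield `r = NA` (excluded from
  the fold mean with `na.rm`); R² and RMSE remain defined.
* Zero bootstrap SD at a voxel flags the voxel, sets p = 1.
* Exactly tied fold differences give t = 0 (or ±Inf with a note when the
  mean is nonzero) in the corrected resampled t-test.
* All stochastic steps (fold assignment, permutations, bootstrap draws,
  surrogate construction, variogram pair subsampling) are seeded;
  identical seeds reproduce bit-identical results, which the pipeline
  manifest's content hashes make verifiable.

## Problem sizes used in the shipped tests

The test suite validates the full default design (34 x 16, ~5000 voxels)
for trial bookkeeping and parameter recovery, and uses reduced designs —
8-10 subjects, 5-6 trials per condition, 10-16 voxel grids — for the
resampling-heavy calibration suites (200 permutation-test repeats at 19
permutations each; 100 similarity-null repeats at 99 surrogates each).
The pipeline's desk-scale defaults are 200 permutations, 200 bootstrap
resamples and 199 surrogates; production-scale counts (5000 / 5000 /
1000) are one flag away (`analysis_config(paper_scale = TRUE)`), and the
add-one p-value convention keeps reduced-replicate inference valid, just
coarser.

## Known limitations

* The generator's hurdle-Gamma coupling between latent brain signal and
  facial score is a stand-in for an unobservable generative process; it is
  exposed as configuration, not asserted as the true model.
* The bootstrap refits on each full resample (no inner cross-validation),
  and the z statistic is the bootstrap mean over SD — conventions chosen
  to match the canonical implementation lineage of this analysis; both
  are documented choices rather than uniquely correct ones.
* The corrected resampled t-test operates on per-fold differences
  (df = J − 1). Comparisons reported per-trial elsewhere are not
  reproduced by this method.
* Volumetric surrogates only; surface-based (spin-test) nulls are out of
  scope.
* With ~70/30 train/test language versus 10-fold grouped cross-validation
  (~90/10), the grouping contract is treated as binding and the
  percentage as descriptive; the package implements grouped 10-fold.
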