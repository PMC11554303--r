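Package: fepsig
Title: Brain Signature Decoding of the Facial Expression of Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to train and evaluate multivariate voxel-weight signatures
    that predict the facial expression of pain from trial-wise fMRI activation
    maps. Implements Facial Action Coding System (FACS) composite scoring and
    behavioral quality-control mixed models, LASSO principal-component
    regression with participant-grouped cross-validation, permutation tests on
    cross-validated performance, bootstrap inference on voxel weights with
    false-discovery-rate thresholding, pattern-expression scoring with
    condition contrasts on estimated marginal means, and spatial similarity of
    weight maps assessed against variogram-matched surrogate maps that preserve
    spatial autocorrelation. A synthetic-data generator produces trial-wise
    activation volumes with a known embedded pattern so the full pipeline can
    be exercised and validated end-to-end without access to participant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
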