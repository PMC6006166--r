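Package: pefmri
Title: Simulation and Permutation Inference for Reward Prediction-Error fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end tools for model-based fMRI studies of reward
    prediction-error signalling in early psychosis. Implements a
    probabilistic monetary learning task (three stimulus pairs with 80/20
    reward, 50/50 bivalent and 80/20 neutral contingencies), Rescorla-Wagner
    Q-learning simulation and maximum-likelihood fitting of choice data,
    win-stay/lose-shift and mixed-ANOVA behavioural analyses, first-level
    GLMs with a double-gamma haemodynamic response, temporal derivatives and
    a value-balanced bivalent-win versus reward-win prediction-error
    contrast, and group-level permutation inference with variance smoothing,
    threshold-free cluster enhancement (TFCE) and max-statistic family-wise
    error correction. A synthetic-cohort generator produces behaviour, ROI
    masks and 4D BOLD data with group-specific prediction-error coupling for
    power analysis and pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
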