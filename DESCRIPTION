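Package: traindiff
Title: Optimal Training Difficulty for Gradient-Descent Learners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for studying how training difficulty
    shapes the speed of learning in binary classification. Provides pluggable
    standardized noise models with exact error rates, learning gradients,
    optimal difficulty and optimal training error rates (the "eighty-five
    percent rule" under Gaussian noise), closed-form and numerically
    integrated learning dynamics under clamped error rate or clamped
    difficulty, a teacher-student perceptron simulator with trial-by-trial
    difficulty clamping, a two-layer sigmoidal network trained by
    backpropagation with teacher-rated difficulty staircasing on synthetic
    image stimuli, a reimplementation of the Law-Gold MT/LIP model of
    perceptual learning with reward-prediction-error weight updates and
    coherence staircasing, and a harness for reproducible parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    jsonlite,
    pracma,
    readr,
    stats,
    tibble,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
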