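Package: cardiohawk
Title: Chaotic Harris Hawks Optimized Attention-GRU and Extreme Learning
    Machine Classification of Cardiac Sensor Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies tabular cardiac sensor records (age, gender, ECG
    summary, blood pressure) from body-area-network cohorts with a
    reservoir-style self-attention gated recurrent unit feature extractor
    and a closed-form regularized extreme learning machine head, whose
    hyperparameters are tuned by Harris Hawks Optimization and its
    logistic-chaotic variant. Includes a synthetic cohort generator with
    the class-conditional blood-pressure and heart-rate structure typical
    of such cohorts, studentized-residual imputation, stratified
    cross-validation and split sweeps, multi-run outcome summaries, and
    Shapiro-Wilk / Wilcoxon signed-rank comparison of optimizer variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
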