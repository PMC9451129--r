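Package: storynf
Title: Simulated Closed-Loop Neurofeedback for Narrative Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully simulated, testable re-implementation of a real-time
    fMRI neurofeedback procedure in which listeners of an ambiguous story
    are nudged toward one of two interpretations ("cheating" vs.
    "paranoid"). Provides synthetic two-group cohort generation with
    station-wise activity templates, per-station L2-regularized logistic
    decoders producing a cheating probability p(c), the pilot-normalized
    score transformation and reward thresholding used for feedback, a
    closed-loop participant agent with probe responses and yoked-control
    mode, post-scan questionnaire scoring (comprehension, interpretation
    bias, empathy differences), and the group-level analyses: per
    participant decoding accuracy, median splits, pooled-variance t tests,
    Pearson correlations and Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
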