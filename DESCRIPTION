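Package: tojpsi
Title: Adaptive PSI Temporal Order Judgment Experiments: Simulation and
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for crossmodal temporal order judgment (TOJ) experiments
    run with the adaptive Bayesian PSI procedure. Implements the logistic
    psychometric model of the point of subjective simultaneity (PSS) and
    slope, a grid-based PSI engine that selects each trial's stimulus onset
    asynchrony by minimizing expected posterior entropy, the factorial
    designs of two nociceptive-cueing TOJ experiments, simulated observers
    embodying prior-entry attention shifts, and the full within-subject
    analysis battery (one-sample t tests with Cohen's d, 2x2
    repeated-measures ANOVA with partial eta squared and contrasts, and
    Cousineau within-subject confidence intervals), together with
    parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
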