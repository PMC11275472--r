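Package: dfncentropy
Title: Trajectory Complexity of Dynamic Functional Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the complexity of subject trajectories through
    functional-connectivity state space in resting-state fMRI. Computes
    tapered sliding-window functional network connectivity (FNC) from
    network time courses, extracts temporally independent FNC profiles via
    PCA whitening and repeated InfoMax ICA consolidated ICASSO-style,
    estimates per-source and joint differential entropy with the
    Kozachenko-Leonenko k-nearest-neighbor estimator, and compares groups
    with permutation, Kolmogorov-Smirnov and normality-gated t tests plus
    covariate-adjusted regressions under FDR control. Includes a seeded
    two-group synthetic-cohort generator with analytic entropy ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
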