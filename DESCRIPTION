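Package: sacsize
Title: Cell-Size Dynamics and Proliferation Statistics Under Chronic
    Spindle-Checkpoint Activation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Stochastic simulation and statistical analysis of budding-yeast
    cell-size homeostasis when the spindle assembly checkpoint (SAC) is
    chronically active. Implements a combined exponential-to-linear
    single-cell growth curve with halving divisions and regime-dependent
    cycle-length distributions (Normal for unperturbed cycles, delayed
    Exponential for SAC-active cycles), in-silico checkpoint-onset and
    checkpoint-withdrawal experiments, an iterative interquartile-range
    filter and moving-average smoother for time-lapse size trajectories,
    local growth-rate estimation and binning, cell-cycle phase statistics
    (fold changes, size-growth slope, coefficients of variation,
    normality-gated correlation choice, density overlap, log-rank
    comparisons), a binomial chromosome mis-segregation to aneuploidy
    probability estimator, and the stress response intensity (SRI) score
    for environmental-stress-response expression profiles, together with
    synthetic-data generators with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
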