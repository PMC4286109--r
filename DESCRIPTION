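Package: swcrt
Title: Power and Detectable Difference for Stepped-Wedge and Parallel
    Cluster Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes power and minimum detectable difference for
    cross-sectional cluster randomised trials whose shape is encoded as a
    design pattern matrix: complete stepped-wedge designs, incomplete
    designs with transition (implementation) periods, staggered parallel
    designs with or without baseline measurement, and designs with two
    nested levels of clustering (e.g. wards within hospitals).  Power is
    obtained from a Wald test using the generalised least squares
    information matrix of the cell-means mixed model, with closed-form
    design-effect routes (including the baseline-adjusted ANCOVA design
    effect) available for parallel designs, and a seeded Monte-Carlo
    simulator for empirical validation of the analytic results.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
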