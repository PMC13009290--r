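Package: resilvar
Title: Growth Resilience Indicators and Genomic Variance Components from
    Longitudinal Fish Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes log-transformed variance of individual growth-curve
    deviations (LnVar) as a resilience indicator from longitudinal body
    weights, following the allometric growth model W = a + b*t^f.  Estimates
    the overall weight exponent by profiled nonlinear least squares, fits
    per-fish linearised growth lines (daily growth coefficient, DGC),
    and derives individual- and cohort-based LnVar.  Builds VanRaden
    method-2 genomic relationship matrices from SNP dosages and estimates
    heritabilities, genetic and phenotypic correlations, and
    cross-environment genetic correlations with an average-information REML
    animal model, including BLUP breeding values.  A synthetic-data module
    emulates a two-pond grow-out experiment with family structure so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
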