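Package: taguchiomega
Title: Taguchi Attribute-Data Analysis with Omega Transformation and a
    Back-Propagation Check for Dialyzer Solidification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproduces an integrated quality-improvement workflow for
    reducing the solidification (clotting) rate of dialyzers in
    hemodialysis: an L9(3^4) Taguchi orthogonal-array experiment over four
    process factors, accumulation analysis of binary (good/defective)
    quality characteristics with smaller-the-better level selection, defect
    rate prediction through the omega (logit-decibel) transformation, and a
    from-scratch feed-forward back-propagation network with momentum used as
    a stability check on the selected factor-level combination.  Includes a
    synthetic-data generator for run-level Bernoulli outcomes and
    categorical patient covariates so the entire pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
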