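Package: screenpolish
Title: Image-Based RNAi Screen Analysis with B-Score Normalization and
    Hit-Funnel Calling
Version: 0.1.0
Authors@R: person("screenpolish", "maintainers", role = c("aut", "cre"),
    email = "maintainers@screenpolish.invalid")
Description: Analysis pipeline for high-content, image-based siRNA screens
    that read out nuclear translocation of a fluorescent reporter.
    Quantifies per-cell nucleus-to-cytoplasm intensity ratios from
    two-channel fields (nuclear stain plus reporter), aggregates them into
    per-well scores, removes 384-well positional artifacts by two-way
    median polish, standardizes residuals into B scores, computes
    Z'-factor plate quality control from control wells, and applies a
    three-stage hit funnel: a primary B-score cutoff, per-siRNA
    deconvolution across two cell lines, and a quantitative-PCR
    bounce-back attenuation filter based on delta-delta-Ct fold changes.
    A synthetic-data module generates microscopy fields, plate score
    matrices with known positional gradients and planted hits, and Ct
    tables with known ground truth, so that every stage of the pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
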