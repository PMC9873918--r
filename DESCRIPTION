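Package: colitraj
Title: Temporal Colitis Signatures from Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives fixed (per-timepoint) and dynamic (disease-by-time
    interaction) gene-expression and exon-usage signatures from time-course
    RNA-seq count matrices of murine colitis models, soft-clusters disease
    trajectories into temporal classes, quantifies adaptive immune burden and
    clonality from VDJ clone tables, builds signature-derived features that
    predict histopathology across cohorts with random forests, and translates
    signatures to human via ortholog projection, AIC-penalized restricted
    cubic spline regression with bootstrap optimism correction, and
    hypergeometric network-overlap tests. Includes a negative-binomial
    synthetic-data generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger
Suggests:
    testthat (>= 3.0.0),
    limma,
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
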