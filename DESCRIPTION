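Package: vertrel
Title: Inter-Rater Reliability of Vertebral Landmark Annotations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-rater landmark annotation studies on
    lumbar spine radiographs: consensus landmark construction, Euclidean and
    per-axis deviation statistics in millimetres, vertebral endplate line
    (UVEL/LVEL) angle measurement, single-rating intraclass correlation under
    the two-way random-effects absolute-agreement model with percentile
    bootstrap confidence intervals, linear mixed-model tests of rater-group
    homogeneity fitted by restricted maximum likelihood, and a synthetic-study
    simulator that reproduces the statistical structure of a two-group,
    twelve-rater lumbar labelling study for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
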