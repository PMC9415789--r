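Package: acrytrend
Title: Harmonization and Time-Trend Analysis of European Acrylamide
    Biomonitoring Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to combine heterogeneous study-level human biomonitoring
    reports of acrylamide exposure into a single harmonized panel of yearly
    mean urinary metabolite concentrations, and to model their time trend.
    Implements mean and standard-deviation estimation from medians with
    ranges or quartiles (Hozo-type order-statistic estimators), conversion
    of hemoglobin-adduct levels in blood to urinary mercapturic-acid
    equivalents via a fitted zero-intercept proportionality factor, the
    study inclusion and year-assignment rules used in European acrylamide
    trend analyses, and three study-size-weighted trend models: multiple
    linear regression, LOESS smoothing, and one-breakpoint segmented
    regression with a parametric-bootstrap breakpoint test. Ships
    transcriptions of the published study tables as fixtures and synthetic
    generators for every input, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
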