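Package: hamet
Title: Cross-Tissue Expression Aggregation and Hyaluronan Size-Distribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for comparative hyaluronan (HA) metabolism
    studies. Implements a sign-weighted Fisher's method statistic that
    aggregates per-tissue differential-expression evidence (p-value and fold
    change direction) into a single cross-tissue p-value per gene via an
    empirically resampled null distribution, together with an unweighted
    Fisher aggregation over gene sets. Also provides RPKM normalization,
    group fold changes and volcano tables for expression matrices;
    size-exclusion chromatography (SEC) elution-profile normalization,
    molecular-weight calibration against standards, high- versus
    low-molecular-weight mass ratios and gel-ladder band sizing; HA
    quantification (standard-curve interpolation, dry-weight normalization)
    with two-group, one-way and two-way comparisons including Holm-Sidak and
    Bonferroni adjustment; and seeded synthetic-data generators so every
    stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
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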