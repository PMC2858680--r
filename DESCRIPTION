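Package: redtime
Title: Replication Timing and Nuclear Localization of Single Telomeres
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the replication timing of individual telomeres from
    chromosome-orientation FISH (CO-FISH / ReDFISH) detargeting scores.
    Classifies two-channel sister-telomere signals into detargeted, mixed and
    unscorable calls, converts per-pulse detargeting counts into normalized
    replication fractions, mean replication timing (mrt) and early/mid/late
    S-phase bins with exact binomial confidence intervals, and compares arms
    with exact contingency-table tests, Spearman rank correlations and
    Bonferroni-corrected thresholds. Also quantifies radial nuclear position
    of 3D FISH spots as equal-volume-shell zones and volume ratios relative
    to the nuclear boundary (ellipsoid models or anisotropic voxel masks),
    and relative telomere length from Q-FISH intensities. A fully seeded
    synthetic-data generator emulates the observational structure of a
    pulse-labelled S phase so every stage of the pipeline can be validated
    end to end without image data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
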