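Package: somatomap
Title: Somatotopic Finger Mapping and Representational Analysis of Simulated BOLD Data
Version: 0.1.0
Authors@R: person("Somatomap", "Developers", email = "somatomap@example.org", role = c("aut", "cre"))
Description: Tools for phase-encoded (travelling-wave) finger somatotopy
    mapping, split-half Dice overlap analysis, blocked-design GLM estimation,
    and cross-validated Mahalanobis (crossnobis) representational similarity
    analysis of primary somatosensory cortex hand maps, together with a
    synthetic BOLD cohort generator with known somatotopic ground truth and a
    graded deterioration parameter. Includes single-case (Crawford-Howell)
    statistics, bootstrap confidence intervals, Benjamini-Hochberg FDR
    control, rank-based group comparisons, and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
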