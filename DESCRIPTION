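Package: immuniche
Title: Immune-Niche Spatial Quantification and Phase 2 Trial Correlative
    Statistics
Version: 0.1.0
Authors@R:
    person("Winship", "Analytics", email = "analytics@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying immune niches in multiplex
    immunofluorescence cell-coordinate data and for the correlative
    statistics of a single-arm phase 2 neoadjuvant trial in clear cell
    renal cell carcinoma. Converts per-cell marker intensities into
    phenotype calls, detects tumor regions where MHC-II+ antigen-presenting
    cells and TCF1+ stem-like CD8+ T cells co-occur above per-mm2 density
    thresholds, and computes niche coverage and nearest-neighbor distance
    statistics. Clinical-side functions implement RECIST 1.1 response
    classification, exact binomial confidence intervals for the objective
    response rate, operating characteristics of Simon two-stage designs,
    Kaplan-Meier survival estimation, rank-based biomarker tests,
    baseline-anchored fold changes, and ctDNA detection and variant
    summaries. A synthetic-cohort generator with known ground truth makes
    every stage testable without access to patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
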