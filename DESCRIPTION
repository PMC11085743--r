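Package: specfx
Title: Spectrum-Effect Screening of Bioactive Components in Multi-Batch Herbal Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for nominating bioactive components of a
    multi-batch herbal extract from chromatographic fingerprints and cell
    bioassay panels. Provides retention-time-tolerance matching of peaks
    across batches into a common-peak matrix, gray relational analysis (GRA)
    between peak-area series and bioactivity indicators, PLS1 regression via
    NIPALS with variable-importance-in-projection (VIP) screening, target-cell
    binding intersection, a from-scratch backpropagation neural-network peak
    classifier, and an orchestrated screening decision with a per-peak trace.
    A synthetic-data generator with planted ground truth makes every stage
    testable without proprietary assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
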