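Package: coevoMI
Title: Mutual Information Co-Evolution Analysis of Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-evolving residue pairs in protein multiple sequence
    alignments by computing the mutual information between alignment columns
    over an extended 22-symbol amino-acid alphabet (20 standard residues, the
    gap character, and a placeholder for non-standard residues). Finite-sample
    bias of the plug-in estimator is corrected with a column-shuffle null model
    of neutral evolution: single-column entropies are preserved while
    inter-column correlation is destroyed, and observed values are mapped to
    per-pair Z-scores. Includes matrix post-processing for visual analysis
    (greedy seed-row/L1 seriation, value-range filtering, weight-by-
    multiplication and saturation weighting, color-mapped lossless PNG export),
    a plain-text triple-per-line matrix interchange format, and a synthetic
    alignment generator with planted coupled column pairs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    Biostrings,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
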