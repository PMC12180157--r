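Package: expanDE
Title: Candidate Gene Prioritization from Gene-Family Expansion and
    Drought Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prioritizes candidate genes for a tolerance trait (drought
    adaptation in Brassicaceae) by intersecting trait-specific,
    ploidy-corrected gene-family expansions with differential expression
    under stress. Reads OrthoFinder-style hierarchical orthogroup (HOG)
    tables and per-species differential-expression results, restricts the
    analysis to the set of families conserved across all study species,
    calls expansions with a configurable fold threshold, classifies
    regulation patterns, evaluates cross-species conservation of
    differential expression against an independence null, composes nested
    candidate tiers, and integrates precomputed diversifying-selection
    tests and GO annotations through exact one-sided hypergeometric
    enrichment statistics. Includes a synthetic-data generator with
    planted effects for calibration and power analysis of the whole
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
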