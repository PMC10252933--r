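Package: depscreen
Title: Lineage-Specific Differential Dependency Screening for Genome-Wide
    Knockout Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for discovering tumor-lineage-specific essential genes in
    genome-wide CRISPR/RNAi gene-effect matrices. Implements one-vs-rest
    two-sample T-statistic screening with top-k selection, dependency-
    probability calls, expression breadth and relative-expression indices
    across cell-line panels, tumor-vs-normal Mann-Whitney differential
    expression with fold-change-median reporting, cross-platform RNAi
    knockdown concordance scoring, Fisher-exact category overrepresentation
    with Benjamini-Hochberg FDR, and expression-dichotomized Kaplan-Meier
    log-rank survival screening. A synthetic-data generator produces
    DepMap-like datasets with known ground truth so every pipeline stage is
    testable without portal downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
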