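Package: harvestgs
Title: Genome-Wide Selection Across Harvests in Perennial Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction pipeline for perennial breeding populations
    evaluated over repeated harvests. Implements marker quality control
    (call rate and a population-size-derived minor-allele-frequency critical
    level), ridge-regression BLUP (RR-BLUP) of marker effects with REML
    variance components solved by spectral decomposition, k-fold
    cross-validation of genomic estimated breeding values, derived selection
    statistics (genomic selection accuracy, implied QTL number, required
    population size, efficiency relative to phenotypic selection), and
    cross-harvest model-transfer validation. Ships a synthetic
    breeding-population generator emulating a multi-parent crossing design
    with replicated block trials, so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
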