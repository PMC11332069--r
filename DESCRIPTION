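Package: chiralome
Title: Untargeted Chiral Metabolomics Analysis with Transcriptome Integration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of untargeted chiral (enantiomer-resolved)
    LC-MS metabolomics feature tables: probabilistic quotient normalization,
    detection of candidate enantiomer pairs from m/z and retention-time
    proximity, verification of pairs through elution-order switching between
    (+)- and (-)-DATAN derivatized quality-control pools, per-feature
    differential testing with significance tiers, and integration with gene
    expression data via coefficient-of-variation filtering, Pearson
    gene-metabolite correlation networks, and joint metabolite-gene pathway
    enrichment (hypergeometric tests, Fisher p-value combination, degree
    centrality impact). Ships a synthetic-data generator with planted ground
    truth so every stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
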