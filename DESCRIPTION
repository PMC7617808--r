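Package: lupustrio
Title: Trio Exome Analysis of Rare and De Novo Variants in Childhood-Onset Lupus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pedigree-aware workflow for trio whole-exome studies of
    childhood-onset systemic lupus erythematosus (SLE): KING-robust
    relatedness verification, Mendelian-consistency and de novo variant
    classification with variant-allele-fraction (VAF) based mosaicism
    flagging, a rare-variant filter cascade (consequence inclusion,
    dual-population gnomAD-style MAF filtering, read-support gates, SLE
    gene-panel intersection, damage-prediction consensus), case-control
    burden statistics, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, and candidate-gene prioritization by
    intersecting top pathways with B-cell expression. A synthetic
    trio-cohort generator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
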