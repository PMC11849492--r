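Package: dermalink
Title: Metagenome-Phenome Association Pipeline for the Skin Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking skin metagenomes to device-scored skin imaging
    phenotypes (SIPs): skin-age indices by cross-validated random-forest
    regression, alpha/beta diversity and PERMANOVA associations, co-abundance
    gene group (CAG) and metagenomic species (MGS) construction by canopy
    clustering with rule-based taxonomy, a KEGG-module versus phenotype
    rank-correlation enrichment statistic, and leave-one-MGS-out driver
    attribution. Includes a synthetic cohort generator that plants known
    age trends, diversity effects and a driver species so every stage of the
    pipeline can be validated against a recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr
Config/testthat/edition: 3
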