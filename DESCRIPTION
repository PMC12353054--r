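Package: dimorphomics
Title: Cross-Omics Analysis of Sexual Dimorphism with Multi-Study Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying sexual dimorphism across proteomic and
    transcriptomic profiles of the same tissue, built around the analyses
    used for human dorsal root ganglion (DRG) data: gene-group
    deduplication and completeness filtering of DIA proteomics matrices,
    empirical-Bayes moderated t-tests for differential protein abundance,
    permutation gene-set enrichment on ranked statistics and
    hypergeometric overrepresentation analysis, supervised PCA against
    externally defined feature lists, multi-study factor analysis with
    ECM estimation, Bartlett factor scores and factor-by-sex ANOVA, and
    background-referenced phospho-array quantification. A synthetic-data
    module generates multi-study latent-factor data with known ground
    truth so every stage can be validated without access to raw
    mass-spectrometry or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    car,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
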