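Package: ssGWAS
Title: Single-Step GBLUP Genome-Wide Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-step genomic BLUP (ssGBLUP) analysis of
    quantitative traits in pedigreed populations with a genotyped subset:
    pedigree relationship matrices (A, sparse A-inverse, inbreeding, A22),
    VanRaden genomic relationships with blending and tuning, the combined
    H-inverse, single-trait animal-model mixed-model equations, AI-REML
    variance-component estimation, SNP effects back-solved from genomic
    breeding values with POSTGSF90-style p-values and Bonferroni
    significance thresholds, pairwise linkage disequilibrium by two-locus
    EM, gene annotation of significant markers and hypergeometric
    term enrichment. Includes a gene-dropping simulator producing
    pedigrees, linked genotypes and phenotypes with known variance
    components, so the full pipeline is testable against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
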