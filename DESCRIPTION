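Package: sonmtf
Title: Phenotype-Constrained Fusion of Molecular Networks and Germline
    Variant Profiles by Orthogonal Non-Negative Matrix Tri-Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint co-clustering of a binary subject-by-gene germline
    variant matrix together with several gene-by-gene molecular
    interaction networks (protein-protein interaction, co-expression,
    genetic interaction) by simultaneous orthogonal non-negative matrix
    tri-factorization with a fixed, phenotype-derived subject factor.
    Includes hard cluster extraction, per-cluster union subnetworks,
    healthy-/disease-specific variant classification, hypergeometric
    annotation enrichment with false discovery rate control, a
    subject-pair stability analysis, a planted-structure synthetic data
    generator, and a small command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
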