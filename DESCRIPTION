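Package: phenosets
Title: Phenotype Gene-Set Collections, Genome-Wide Phenotype Models, and
    Parametric Gene-Set Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives non-redundant phenotype gene-set collections from
    curated gene-phenotype association tables (WormBase-style phenotype/gene
    pair lists and FlyBase-style allele phenotype rows), models genome-wide
    phenotype relationships by overlap-coefficient distances and
    Fitch-Margoliash weighted least-squares trees, scores gene sets against
    expression contrasts with the parametric PAGE Z statistic (with Z-ratio
    preprocessing, normal-theory p-values and Benjamini-Hochberg FDR), and
    projects samples by singular value decomposition of row-centered
    gene-set Z matrices.  A seeded synthetic-data generator with a
    ground-truth ledger makes every pipeline stage testable without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
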