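Package: mirescreen
Title: Pooled shRNA Screen Enrichment and Single-Cell Hairpin Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Couples pooled shRNA senescence-bypass screens with single-cell
    RNA-seq. Quantifies shRNA representation from barcoded amplicon reads and
    ranks hairpins by enrichment over a culture time course using a
    negative-binomial exact-style test with empirical-Bayes dispersion
    shrinkage, trimmed-mean-of-M-values normalization, Fisher-combined
    replicate p-values and Benjamini-Hochberg false discovery rates. Detects
    miR-E-embedded hairpins inside poly-A-primed single-cell transcriptome
    reads by guide matching anchored in the scaffold backbone, assigns cells
    to perturbations, and characterizes each perturbation's expression
    profile via bootstrap-stable hierarchical clustering, exact t-SNE
    embedding, rank-sum marker testing, running-sum gene-set enrichment and
    dropout-tolerant signature scoring. Includes seeded simulators with
    planted ground truth for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    cluster
Config/testthat/edition: 3
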