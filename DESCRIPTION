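Package: metadeg
Title: Multi-Study Differential Expression Meta-Analysis, Hub Genes, and
    Over-Representation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An evidence-synthesis workflow for multi-study two-group gene
    expression data. Per-study preprocessing and empirical-Bayes moderated
    differential expression produce fold-change tables with confidence
    intervals; three meta-analytic strategies (DerSimonian-Laird
    random-effects fold-change synthesis, vote counting with sign
    consistency, and Fisher p-value combining) extract the most
    consistently perturbed genes; interaction-network centrality (degree,
    closeness, betweenness) demarcates hub genes; and a hypergeometric
    over-representation engine with deviation-formula odds ratios and
    combined scores performs downstream gene-set analysis. A seeded
    synthetic-data generator emulates multi-tissue microarray collections
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
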