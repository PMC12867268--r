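Package: chemtwas
Title: Summary-Statistics TWAS and Chemical Gene-Set Enrichment with PPI
    Post-Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative gene-environment analysis toolkit for complex
    disease. Computes per-gene transcriptome-wide association (TWAS)
    Z-statistics from GWAS summary statistics, eQTL weight panels and LD
    reference matrices; tests chemical-gene interaction sets against the
    resulting gene ranking with a weighted Kolmogorov-Smirnov enrichment
    statistic and a permutation-based normalized enrichment score; performs
    two-group differential expression with fold-change and FDR thresholds;
    and post-processes protein-protein interaction networks with MCODE
    module detection and Maximal Clique Centrality, Edge Percolated
    Component and Degree hub scoring. Ships a synthetic-data generator that
    emulates blockwise LD, sparse cis weight panels, GWAS Z-vectors with
    planted causal genes, chemical sets with planted enrichment, two-group
    expression matrices and graphs with planted dense modules, together
    with a ground-truth ledger for parameter-recovery testing, and a
    pipeline driver that runs every stage from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
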