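Package: proxscreen
Title: Multi-Tissue Differential Expression, Signature Correlation and
    Network Drug-Target Proximity Screening
Version: 0.1.0
Authors@R:
    person("proxscreen", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for hypothesis-generating analysis of multi-tissue
    treated-vs-control transcriptome experiments. Implements read-level
    FASTQ quality filtering, FPKM normalization, a self-contained
    negative-binomial exact test for per-tissue differential expression,
    cross-study log2 fold-change signature comparison by Spearman
    correlation with redundancy pruning and Bonferroni correction, a
    network-based drug-target proximity statistic with a permutation null
    and empirical FDR plus a two-source consensus rule, generic
    hypergeometric/Fisher over-representation machinery for gene sets and
    drug annotations, ortholog mapping, and a seeded synthetic-data
    generator that plants known differential expression, signature
    correlations and network-proximal drugs so every stage can be tested
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    S4Vectors,
    ape,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
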