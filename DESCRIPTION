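Package: degnet
Title: Differential Expression and Interaction-Network Hub Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end network transcriptomics for two-condition bulk RNA-seq:
    negative-binomial Wald tests on median-of-ratios normalized counts with
    Benjamini-Hochberg correction, construction of a confidence-filtered
    protein-protein interaction network restricted to differentially expressed
    genes using STRING-style evidence-channel score recombination, extraction
    of the highest-diameter subnetwork, removal of ribosomal-protein nodes,
    hub discovery by degree and betweenness centrality, and hypergeometric
    over-representation analysis ranked by fold enrichment. Includes a seeded
    synthetic-data generator with planted differential expression, a planted
    hub cluster, a ribosomal clique, and text-mining-only decoy interactions
    for ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
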