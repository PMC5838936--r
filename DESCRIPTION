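Package: coreClust
Title: Alignment-Free Clustering of Protein Conserved Regions by Min-Wise
    Hashing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Clusters conserved regions of protein sequences without
    alignments. Regions are reduced to k-mer sets, compared through
    two levels of min-wise independent hashing ((k,c)-sketches bucketed
    per hash function), and the resulting similarity graph is clustered
    with Louvain community detection. The hash-function family is grown
    iteratively, reusing sketches incrementally, until a weighted
    two-sided F1 score between the current clustering and an earlier one
    exceeds a threshold. Region clusters are extended to possibly
    overlapping protein clusters. Includes a synthetic protein-family
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
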