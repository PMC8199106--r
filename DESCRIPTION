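Package: rhizomer
Title: Genome Mosaicism Profiles, ORFan Calling and Phyletic-Pattern Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genome mosaicism ("rhizome") profiles by attributing each
    protein-coding gene of a query genome to the taxonomic origin group of its
    best surviving database hit, after excluding hits from the query's own
    genus or taxon and applying identity, query-coverage and e-value
    thresholds; genes with no surviving homolog are called ORFans. Ships a
    Smith-Waterman affine-gap protein aligner with Karlin-Altschul e-value
    statistics, an adapter for precomputed 12-column tabular hit files,
    rhizome network export (GEXF), phyletic presence/absence (0/1) matrix
    construction against reference gene-family sets with Euclidean-distance
    hierarchical clustering, and a seeded synthetic-data generator that plants
    known origin proportions, ORFan fractions and group-specific family
    presence probabilities for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    ape,
    xml2,
    jsonlite,
    yaml,
    mclust,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
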