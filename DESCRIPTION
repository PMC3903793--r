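Package: piface
Title: Protein-Protein Interface Extraction, Structural Clustering and
    Template Libraries
Version: 0.1.0
Authors@R:
    person("PIFACE", "Maintainers", email = "piface@example.org",
           role = c("aut", "cre"))
Description: Extracts protein-protein interface structures (contact and
    nearby residues) from multi-chain coordinate files, scores pairwise
    interface similarity by non-sequential (sequence-order-independent)
    structural alignment, clusters the resulting interface-similarity
    network with a node-grouping-accelerated Girvan-Newman edge-betweenness
    community-finding algorithm, validates clusterings with the silhouette
    index, and derives downstream products: cluster representatives,
    relative-accessible-surface-area (RASA) based surface extraction for
    template-based docking, and detection of protein pairs that bind
    through multiple distinct interface architectures. Includes a
    Shrake-Rupley accessible-surface-area engine and generators for
    synthetic toy complexes and planted-community similarity networks used
    throughout the test suite.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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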