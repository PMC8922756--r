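Package: plastidscape
Title: Plastome Characterization and Plastid Gene-Tree Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of annotated plastid genomes and the
    landscape of the gene trees they encode. Provides sliding-window
    nucleotide diversity with hotspot screening, perfect-microsatellite
    (SSR) scanning with class-specific unit minima, exact inverted-repeat
    detection with quadripartite partitioning and junction reports, gene
    presence/absence across accessions, Nei-Gojobori (1986) pathway-averaged
    dN/dS with Jukes-Cantor correction and functional-group rate
    comparisons, distance-based gene-tree inference with bootstrap and
    low-support collapsing, Robinson-Foulds tree space with principal
    coordinates, silhouette-selected Ward clustering of gene trees, a
    gene-tree discordance metric, PhyParts-style per-edge concordance
    counting, and a quartet-support species-tree estimator. A synthetic-data
    module generates species trees, discordance-regime gene trees,
    nucleotide and codon alignments, and whole plastomes with planted
    inverted repeats, SSRs and gene losses, together with machine-readable
    ground truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    cluster,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
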