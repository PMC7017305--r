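Package: splicenet
Title: Differential Expression and Interaction-Network Topology of the
    Splicing Machinery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for studying deregulation of the
    spliceosome and its auxiliary factors across tissues and disease
    subtypes from microarray expression data. Normalizes probe-level
    intensities (threshold to 1, log2, per-row median baselining),
    restricts the matrix to an a-priori splicing-gene panel, collapses
    probes to genes, fits per-gene two-way ANOVA (tissue x disease state,
    Type-III sums of squares) with Benjamini-Hochberg FDR control, screens
    seven study contrasts by fold change, tests gene-set
    overrepresentation with one-sided Fisher's exact tests and Bonferroni
    correction, and builds first-order protein-protein interaction
    networks from DEG seeds over a scored tissue-specific interactome,
    classifying hub-bottleneck and nonhub-bottleneck nodes by degree and
    betweenness centrality. A synthetic-data module generates factorial
    expression datasets, scale-free scored interactomes and annotation
    sets with planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
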