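Package: tknet
Title: Transkingdom Multi-Omics Correlation Networks and Compartment
    Topology Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and topological comparison of transkingdom
    association networks that integrate gut microbiota with host omic
    layers (transcriptome, metabolome, phenotypes) across two intestinal
    compartments and two diet groups. Implements compositional (CLR)
    normalization and differential screening, per-group Spearman
    correlation with Fisher meta-analysis, sign-consistency and
    fold-change-coherence edge filtering, and a topology suite:
    retention chi-square comparison, bipartite edge counts, degree
    power-law diagnostics, bipartite betweenness centrality (BIBC),
    set-to-set shortest-path closeness with Wilcoxon comparison, dense
    subnetwork detection, and hypergeometric over-representation
    analysis. Ships a latent-factor synthetic multi-omics generator with
    planted cross-kingdom coupling so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    car,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
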