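Package: guildquant
Title: Quantification of Microbial Guilds from Phylogenetic Placements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the contribution of microbial taxa to functional
    guilds from metagenomic data. Query sequences placed on an annotated
    reference gene tree (jplace format) are classified into functional
    sequence spaces ("implementations"), and each (taxon, implementation,
    environment) group is scored with an impact coefficient that combines
    abundance, observed versus expected sequence richness under a fitted
    power law, and functional univocity. Also provides the two supporting
    tree statistics: a leaf-trait randomization test that discovers
    trait-enriched internal nodes, and a two-phylomarker patristic-distance
    null model that flags gene-tree nodes whose divergence departs from
    taxonomy. A synthetic-data module generates trees, trait tables,
    placements and abundance tables with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    phytools,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
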