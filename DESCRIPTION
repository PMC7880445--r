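Package: keggsim
Title: Two-Level Reconstruction and Comparison of KEGG Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs an organism's metabolism from KGML (KEGG Markup
    Language) pathway files into a two-level representation: a structural
    graph whose nodes are reference pathways joined when they share at least
    one non-ubiquitous compound, and a functional level holding each
    pathway's reaction set or multiset. Provides case-based local similarity
    indexes per pathway and four global indexes (pathway, weighted pathway,
    structure, combined) for pairwise organism comparison, all-pairs
    similarity matrices with complete-linkage hierarchical clustering,
    colour-map rendering, GraphML/DOT/TSV/CSV/Newick export, an optional
    KEGG REST client with on-disk caching, and a seeded synthetic KGML
    fixture generator with an independent brute-force oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    igraph,
    ape,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
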