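Package: genenetval
Title: Biological Validity of Inferred Gene Networks Against KEGG Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts KEGG metabolic pathways (KGML files) into undirected
    gene association networks and scores the biological validity of an
    inferred gene network against them with a level-weighted matching
    distance: an input edge whose endpoints lie at shortest-path distance l
    in the gold standard contributes 1/l to the cumulative hit count.
    Includes pathway-specific pruning, a classical precision baseline,
    ROC analysis against pure-random and scale-free null networks,
    a noise-degradation study, construction of an organism-wide global
    network, per-pathway functional assignment, a synthetic KGML fixture
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
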