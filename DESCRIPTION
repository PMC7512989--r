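Package: cnsnet
Title: Coupled Node Similarity and Community Detection for Attributed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for community detection in undirected networks whose nodes
    carry categorical attributes. Implements coupled node similarity (CNS), a
    node-pair similarity that fuses the frequency-based intra-attribute coupled
    similarity of attribute values, the co-occurrence-based inter-attribute
    coupled similarity between attributes, and a homophily-driven
    attribute-to-structure consistency term. Similarities weight the edges of
    the plain graph, and communities are detected on the weighted graph with
    speaker-listener label propagation (SLPA), weighted-modularity Louvain
    optimisation (BGLL), or similarity-based K-medoids. Includes partition
    quality metrics (NMI, F-measure, matching accuracy), a planted-partition
    generator for attributed benchmark networks with three attribute
    assignment rules, and tidy accessors and plots for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
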