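Package: contricent
Title: Contribution Centrality for Undirected Networks via Neighbourhood
    Dissimilarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Ranks nodes of undirected networks with contribution
    centrality, an eigenvector centrality in which each neighbour's
    contribution is weighted by the structural (Jaccard or Tanimoto)
    dissimilarity between the two nodes' neighbourhoods: scores are the
    dominant eigenvector of the entrywise product of the adjacency matrix
    and a dissimilarity matrix.  Ships the six classical comparison
    measures (degree, eigenvector, betweenness, closeness, information and
    communicability centrality), edge-list and GML readers, bundled
    benchmark networks (Zachary karate club, Padgett Florentine marriages,
    Les Miserables coappearances), a Barabasi-Albert generator, ranking
    and rank-agreement tooling, ggplot2 visualisations and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
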