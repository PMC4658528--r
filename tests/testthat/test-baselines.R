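test_that("degree centrality counts connections", {
  s <- scores_of(degree_centrality(star_graph(3)))
  expect_equal(unname(s["1"]), 3)
  expect_equal(unname(s[c("2", "3", "4")]), rep(1, 3))
  expect_equal(unname(scores_of(degree_centrality(netgraph(nodes = "a")))), 0)
})

test_that("shortest-path census counts geodesics correctly", {
  cen <- shortest_path_census(path_graph(3))
  expect_equal(cen$dist["1", "3"], 2)
  expect_equal(cen$sigma["1", "3"], 1)
  expect_equal(paths_through(cen, "2")["1", "3"], 1)

  c4 <- shortest_path_census(cycle_graph(4))
  expect_equal(c4$sigma["1", "3"], 2)  # two opposite-corner geodesics
  expect_equal(c4$dist["1", "3"], 2)

  dis <- shortest_path_census(netgraph(edges_df("a", "b"), nodes = "z"))
  expect_equal(dis$dist["a", "z"], Inf)
  expect_equal(dis$sigma["a", "z"], 0)
})

test_that("betweenness matches the explicit path-census brute force", {
  b3 <- scores_of(betweenness_centrality(path_graph(3)))
  expect_equal(unname(b3), c(0, 1, 0))

  expect_equal(max(scores_of(betweenness_centrality(complete_graph(5)))), 0)

  for (seed in 1:60) {
    n <- 4 + (seed %% 4)  # sizes 4..7
    g <- random_connected_graph(n, 0.4, seed)
    got <- scores_of(betweenness_centrality(g))
    want <- census_betweenness(g)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("closeness follows the per-component inverse mean distance", {
  s <- scores_of(closeness_centrality(path_graph(3)))
  expect_equal(unname(s), c(2 / 3, 1, 2 / 3))

  expect_equal(unname(scores_of(closeness_centrality(complete_graph(4)))),
               rep(1, 4))

  # disconnected: per component; singleton scores 0 with a warning
  g <- netgraph(edges_df(c("a", "b"), c("b", "c")), nodes = "z")
  expect_warning(s2 <- scores_of(closeness_centrality(g)), "singleton")
  expect_equal(unname(s2["z"]), 0)
  expect_equal(unname(s2["b"]), 1)

  # cross-check against igraph on connected random graphs
  for (seed in 1:10) {
    g <- random_connected_graph(8, 0.3, seed)
    got <- scores_of(closeness_centrality(g))
    want <- igraph::closeness(contricent:::as_igraph(g),
                              normalized = TRUE)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("eigenvector centrality solves the adjacency eigenproblem", {
  st <- scores_of(eigenvector_centrality(star_graph(3)))
  expect_equal(unname(st["1"] / st["2"]), sqrt(3), tolerance = 1e-8)

  expect_equal(unname(scores_of(eigenvector_centrality(cycle_graph(6)))),
               rep(1 / sqrt(6), 6), tolerance = 1e-8)

  # agrees with igraph's eigenvector centrality up to normalisation
  g <- load_fixture("karate")
  got <- scores_of(eigenvector_centrality(g))
  want <- igraph::eigen_centrality(contricent:::as_igraph(g))$vector
  want <- want / sqrt(sum(want^2))
  expect_equal(got, want[names(got)], tolerance = 1e-6)
})

test_that("information centrality realises the inverse-matrix formulation", {
  # single edge: B = L + J = 2 I, C = I / 2, I_ab = 1, both scores 1
  s <- scores_of(information_centrality(netgraph(edges_df("a", "b"))))
  expect_equal(unname(s), c(1, 1), tolerance = 1e-12)

  sv <- scores_of(information_centrality(cycle_graph(5)))
  expect_equal(max(sv) - min(sv), 0, tolerance = 1e-12)

  # centre of a star carries more information flow than the leaves
  st <- scores_of(information_centrality(star_graph(4)))
  expect_gt(st["1"], st["2"])

  g <- netgraph(edges_df("a", "b"), nodes = "z")
  expect_warning(sz <- scores_of(information_centrality(g)), "singleton")
  expect_equal(unname(sz["z"]), 0)
})

test_that("communicability equals the truncated walk series", {
  k2 <- scores_of(communicability_centrality(netgraph(edges_df("a", "b"))))
  expect_equal(unname(k2), rep(cosh(1), 2), tolerance = 1e-10)

  tri <- scores_of(communicability_centrality(complete_graph(3)))
  expect_equal(unname(tri), rep((exp(2) + 2 * exp(-1)) / 3, 3),
               tolerance = 1e-10)

  for (seed in 1:20) {
    n <- 5 + (seed %% 6)  # sizes 5..10
    g <- random_graph(n, 0.35, seed + 100)
    got <- scores_of(communicability_centrality(g))
    want <- series_communicability(g, terms = 30L)
    expect_equal(got, want[names(got)], tolerance = 1e-8)
    expect_true(all(got >= 1))  # the length-0 closed walk
  }
})

test_that("all seven measures are uniform on vertex-transitive graphs", {
  vt <- list(cycle_graph(6), complete_graph(5), cycle_graph(7))
  for (g in vt) {
    for (m in c("degree", "eigenvector", "betweenness", "closeness",
                "information", "communicability")) {
      s <- scores_of(centrality(g, m))
      expect_lt(max(s) - min(s), 1e-8)
    }
    s <- scores_of(contribution_centrality(g, convention = "open"))
    expect_lt(max(s) - min(s), 1e-8)
  }
  # closed convention on cycles (complete graphs are degenerate there)
  s <- scores_of(contribution_centrality(cycle_graph(6),
                                         convention = "closed"))
  expect_lt(max(s) - min(s), 1e-8)
})

test_that("scores are nonnegative across measures and random graphs", {
  for (seed in 1:6) {
    g <- random_connected_graph(9, 0.3, seed + 50)
    for (m in c("degree", "eigenvector", "betweenness", "closeness",
                "information", "communicability")) {
      expect_true(all(scores_of(centrality(g, m)) >= 0))
    }
  }
})
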