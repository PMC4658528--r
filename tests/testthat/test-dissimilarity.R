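test_that("Jaccard dissimilarity matches hand-enumerated values", {
  p3 <- neighborhoods(path_graph(3), "open")
  expect_equal(jaccard_dissimilarity(p3, "1", "3"), 0)  # same nbhd {2}
  expect_equal(jaccard_dissimilarity(p3, "1", "2"), 1)

  e1 <- neighborhoods(netgraph(edges_df("a", "b")), "open")
  expect_equal(jaccard_dissimilarity(e1, "a", "b"), 1)  # disjoint

  tri <- neighborhoods(complete_graph(3), "open")
  expect_equal(jaccard_dissimilarity(tri, "1", "2"), 2 / 3)

  for (n in 4:6) {  # complete graph: |intersect| = n - 2, |union| = n
    nm <- neighborhoods(complete_graph(n), "open")
    expect_equal(jaccard_dissimilarity(nm, "1", "2"), 2 / n)
  }

  # closed neighbourhoods of K_3 are all identical
  tri_c <- neighborhoods(complete_graph(3), "closed")
  expect_equal(jaccard_dissimilarity(tri_c, "1", "3"), 0)

  iso <- neighborhoods(netgraph(nodes = c("u", "v")), "open")
  expect_warning(d <- jaccard_dissimilarity(iso, "u", "v"), "empty")
  expect_equal(d, 0)

  expect_error(jaccard_dissimilarity(p3, "1", "zzz"), "not present")
})

test_that("dissimilarity matrices are symmetric, in range, zero-diagonal", {
  D <- dissimilarity_matrix(path_graph(3), convention = "open",
                            sparse = FALSE)$values
  expect_equal(D["1", "2"], 1)
  expect_equal(D["2", "3"], 1)
  expect_equal(D["1", "3"], 0)

  for (seed in 1:15) {
    g <- random_connected_graph(8, 0.3, seed)
    for (conv in c("open", "closed")) {
      D <- dissimilarity_matrix(g, convention = conv, sparse = FALSE)
      M <- as.matrix(D)
      expect_equal(M, t(M))
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(diag(M)), rep(0, 8))
      # sparse mode agrees on adjacent pairs
      Ms <- as.matrix(dissimilarity_matrix(g, convention = conv))
      A <- adjacency_matrix(g, sparse = FALSE)
      expect_equal(M[A > 0], Ms[A > 0])
    }
  }
})

test_that("Jaccard is zero exactly for twin nodes", {
  # u and v are non-adjacent twins: both see {a, b} and nothing else
  g <- netgraph(edges_df(c("u", "u", "v", "v", "a"),
                         c("a", "b", "a", "b", "b")))
  nm <- neighborhoods(g, "open")
  expect_equal(jaccard_dissimilarity(nm, "u", "v"), 0)
  # any non-twin pair in a seeded random graph has d > 0
  for (seed in 1:10) {
    g2 <- random_connected_graph(7, 0.35, seed)
    nm2 <- neighborhoods(g2, "open")
    for (i in g2$nodes) {
      for (j in g2$nodes) {
        if (i < j) {
          d <- suppressWarnings(jaccard_dissimilarity(nm2, i, j))
          expect_equal(d == 0, setequal(nm2[[i]], nm2[[j]]))
        }
      }
    }
  }
})

test_that("Tanimoto reduces to open Jaccard on 0/1 rows", {
  tri <- complete_graph(3)
  expect_equal(tanimoto_dissimilarity(tri, "1", "2"), 2 / 3)

  # identical rows -> 0 : twins in a weighted graph
  gw <- netgraph(edges_df(c("u", "u", "v", "v"), c("a", "b", "a", "b"),
                          weight = c(2, 3, 2, 3)))
  expect_equal(tanimoto_dissimilarity(gw, "u", "v"), 0)

  # orthogonal rows -> 1
  ge <- netgraph(edges_df(c("a", "c"), c("b", "d"), weight = c(2, 5)))
  expect_equal(tanimoto_dissimilarity(ge, "a", "c"), 1)

  # machine-precision agreement with Jaccard on random unweighted graphs
  for (seed in 1:8) {
    g <- random_connected_graph(7, 0.4, seed)
    Dt <- as.matrix(dissimilarity_matrix(g, "tanimoto", sparse = FALSE))
    Dj <- as.matrix(dissimilarity_matrix(g, "jaccard", convention = "open",
                                         sparse = FALSE))
    expect_equal(Dt, Dj, tolerance = 1e-14)
  }

  # negative weights are rejected at graph construction
  expect_error(netgraph(edges_df("a", "b", weight = -1)), "positive")
})

test_that("weight matrix W = A o D inherits structure from A", {
  tri <- complete_graph(3)
  A <- adjacency_matrix(tri)
  W <- contribution_weight_matrix(
    A, dissimilarity_matrix(tri, convention = "open"))
  expect_equal(as.matrix(W), (2 / 3) * as.matrix(A),
               ignore_attr = TRUE)

  # triangle-free graphs: W = A exactly under (jaccard, open)
  for (g in list(path_graph(5), cycle_graph(4), cycle_graph(6),
                 star_graph(4))) {
    W <- contribution_weight_matrix(
      adjacency_matrix(g), dissimilarity_matrix(g, convention = "open"))
    expect_equal(as.matrix(W), adjacency_matrix(g, sparse = FALSE),
                 ignore_attr = TRUE)
  }

  # all-zero D gives W = 0
  g <- path_graph(3)
  D0 <- dissimilarity_matrix(g)
  D0$values <- D0$values * 0
  expect_equal(max(abs(contribution_weight_matrix(adjacency_matrix(g),
                                                  D0)$values)), 0)

  # mismatched node order is an error
  g2 <- netgraph(edges_df(c("3", "2"), c("2", "1")))
  expect_error(
    contribution_weight_matrix(adjacency_matrix(g2),
                               dissimilarity_matrix(path_graph(3))),
    "node order"
  )

  # support, symmetry, nonnegativity on random graphs, both conventions
  for (seed in 1:10) {
    g <- random_connected_graph(8, 0.35, seed)
    A <- adjacency_matrix(g, sparse = FALSE)
    for (conv in c("open", "closed")) {
      W <- as.matrix(contribution_weight_matrix(
        adjacency_matrix(g), dissimilarity_matrix(g, convention = conv)))
      expect_equal(W, t(W))
      expect_true(all(W >= 0))
      expect_true(all(W <= A + 1e-15))
      expect_true(all(W[A == 0] == 0))
      expect_equal(unname(diag(W)), rep(0, 8))
    }
  }
})

test_that("measure registry accepts, checks and rejects plugins", {
  withr::defer({
    for (m in c("one", "zero", "jaccard2", "bad"))
      contricent:::deregister_measure(m)
  })

  register_measure("one", function(i, j, nm, g) 1)
  g <- complete_graph(4)
  res_one <- contribution_centrality(g, measure = "one")
  res_eig <- eigenvector_centrality(g)
  expect_equal(scores_of(res_one), scores_of(res_eig), tolerance = 1e-8)

  register_measure("zero", function(i, j, nm, g) 0)
  expect_error(contribution_centrality(g, measure = "zero"), "degenerate")

  register_measure("jaccard2", function(i, j, nm, g)
    jaccard_dissimilarity(nm, i, j))
  expect_equal(
    scores_of(contribution_centrality(load_fixture("florentine"),
                                      measure = "jaccard2")),
    scores_of(contribution_centrality(load_fixture("florentine"))),
    tolerance = 1e-9
  )

  expect_error(register_measure("jaccard", identity), "already registered")
  register_measure("bad", function(i, j, nm, g) 1.5)
  expect_error(dissimilarity_matrix(path_graph(3), measure = "bad"),
               "\\[0, 1\\]")
  expect_error(dissimilarity_matrix(path_graph(3), measure = "nosuch"),
               "unknown")
})
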