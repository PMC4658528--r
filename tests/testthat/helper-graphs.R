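# Graph builders and independent oracles shared across the test files.
# All fixtures are built in code; all randomness is seeded.

edges_df <- function(from, to, weight = NULL) {
  df <- data.frame(from = as.character(from), to = as.character(to),
                   stringsAsFactors = FALSE)
  if (!is.null(weight)) df$weight <- weight
  df
}

path_graph <- function(n) {
  netgraph(edges_df(seq_len(n - 1), seq_len(n - 1) + 1))
}

cycle_graph <- function(n) {
  netgraph(edges_df(seq_len(n), c(seq_len(n - 1) + 1, 1)))
}

complete_graph <- function(n) {
  p <- t(utils::combn(n, 2))
  netgraph(edges_df(p[, 1], p[, 2]))
}

# star with centre "1" and n_leaves leaves
star_graph <- function(n_leaves) {
  netgraph(edges_df(rep(1, n_leaves), seq_len(n_leaves) + 1))
}

# Erdos-Renyi G(n, p); not necessarily connected
random_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    netgraph(edges_df(pairs[keep, 1], pairs[keep, 2]),
             nodes = as.character(seq_len(n)))
  })
}

# connected random graph: a random spanning tree plus G(n, p) extras
random_connected_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    perm <- sample(n)
    tree_from <- perm[2:n]
    tree_to <- vapply(2:n, function(k) perm[sample.int(k - 1, 1)],
                      integer(1))
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    df <- edges_df(c(tree_from, pairs[keep, 1]),
                   c(tree_to, pairs[keep, 2]))
    suppressWarnings(netgraph(df, nodes = as.character(seq_len(n))))
  })
}

# ---- independent oracles ------------------------------------------------

# dense dominant eigenpair via base eigen(), sign-aligned
dense_dominant <- function(M) {
  eg <- eigen(as.matrix(M), symmetric = TRUE)
  v <- eg$vectors[, 1L]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(value = eg$values[1L], vector = v)
}

# betweenness by explicit pair-census summation (independent of Brandes)
census_betweenness <- function(g) {
  cen <- shortest_path_census(g)
  nodes <- cen$order
  b <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    thr <- paths_through(cen, nodes[i])
    ratio <- thr / cen$sigma
    ratio[!is.finite(ratio)] <- 0
    b[i] <- sum(ratio[upper.tri(ratio)])
  }
  b
}

# communicability by truncated power series sum_{p<=terms} (A^p)_ii / p!
series_communicability <- function(g, terms = 30L) {
  A <- adjacency_matrix(g, sparse = FALSE, weighted = FALSE)
  n <- nrow(A)
  acc <- diag(n)
  P <- diag(n)
  fact <- 1
  for (p in seq_len(terms)) {
    P <- P %*% A
    fact <- fact * p
    acc <- acc + P / fact
  }
  stats::setNames(diag(acc), rownames(A))
}

# Kendall tau-b by O(n^2) concordant/discordant pair counting
tau_b_bruteforce <- function(x, y) {
  n <- length(x)
  nc <- 0L; nd <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) nc <- nc + 1L
      if (s < 0) nd <- nd + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  t1 <- sum(choose(table(x), 2))
  t2 <- sum(choose(table(y), 2))
  (nc - nd) / sqrt((n0 - t1) * (n0 - t2))
}

# named score vector of a centrality_result
scores_of <- function(res) {
  stats::setNames(res$scores$score, res$scores$node)
}

# enumerate all labelled graphs on n nodes as edge-subset masks and call
# fn(A) for each connected one (A a dense 0/1 matrix)
for_each_connected_graph <- function(n, fn) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  for (mask in seq_len(2^m - 1L)) {
    sel <- as.logical(intToBits(mask)[seq_len(m)])
    A <- matrix(0, n, n)
    A[pairs[sel, , drop = FALSE]] <- 1
    A <- A + t(A)
    R <- diag(n) + A
    P <- R
    for (k in seq_len(n - 2)) P <- P %*% R
    if (all(P > 0)) fn(A)
  }
  invisible(NULL)
}

graph_from_dense <- function(A) {
  labs <- rownames(A)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  netgraph(edges_df(labs[idx[, 1]], labs[idx[, 2]]), nodes = labs)
}
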