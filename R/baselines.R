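# The six classical comparison measures.  All take a graph (netgraph or
# edge data frame), treat it as unweighted topology, and return a
# centrality_result so rankings, tidiers and plots work uniformly.

#' Degree centrality
#'
#' Score of a node = its number of connections (raw counts; any
#' normalisation is ranking-equivalent).
#'
#' @inheritParams contribution_centrality
#' @return A `centrality_result`.
#' @examples
#' tidy(degree_centrality(load_fixture("karate")))[1:3, ]
#' @export
degree_centrality <- function(data) {
  g <- as_netgraph(data)
  ij <- edge_indices(g)
  deg <- tabulate(c(ij[, 1L], ij[, 2L]), nbins = length(g$nodes))
  new_centrality_result(stats::setNames(as.numeric(deg), g$nodes),
                        method = "degree", g = g)
}

#' Eigenvector centrality
#'
#' Centrality proportional to the sum of the centralities of a node's
#' neighbours: the dominant eigenvector of the adjacency matrix, computed
#' with the same shifted power iteration as the contribution method.
#' Disconnected graphs are handled per component with a warning.
#'
#' @inheritParams contribution_centrality
#' @return A `centrality_result` with unit-norm nonnegative scores.
#' @export
eigenvector_centrality <- function(data, tol = 1e-10, max_iter = 10000L) {
  g <- as_netgraph(data)
  if (length(g$nodes) == 0L) stop("empty graph", call. = FALSE)
  A <- adjacency_matrix(g, weighted = FALSE)
  sp <- spectral_scores(A, g, tol, max_iter, "eigenvector centrality")
  new_centrality_result(
    sp$scores, method = "eigenvector", g = g,
    eigenvalue = max_or_na(sp$components$eigenvalue),
    converged = TRUE,
    iterations = max(sp$components$iterations, 0L, na.rm = TRUE),
    residual = max_or_na(sp$components$residual), tol = tol,
    components = sp$components
  )
}

max_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else max(x)
}

#' All-pairs shortest-path census
#'
#' Breadth-first distances and shortest-path counts between all node
#' pairs, the raw material of betweenness and closeness centrality.
#' `paths_through()` derives, for a fixed inner node `i`, the matrix of
#' counts of `j`-`k` geodesics passing through `i`, via the composition
#' identity `sigma_jk(i) = sigma_ji * sigma_ik` when
#' `d(j,i) + d(i,k) = d(j,k)` (and 0 otherwise).
#'
#' @inheritParams contribution_centrality
#' @return `shortest_path_census()`: an object of class `sp_census`,
#'   list with `dist` (matrix, `Inf` for disconnected pairs, 0 diagonal)
#'   and `sigma` (geodesic counts; 0 for disconnected pairs, 1 on the
#'   diagonal), both with node-label dimnames.
#' @examples
#' cen <- shortest_path_census(data.frame(from = c("a", "b"), to = c("b", "c")))
#' cen$dist["a", "c"]
#' paths_through(cen, "b")["a", "c"]
#' @export
shortest_path_census <- function(data) {
  g <- as_netgraph(data)
  n <- length(g$nodes)
  nb <- neighbor_index_list(g)
  dist <- matrix(Inf, n, n, dimnames = list(g$nodes, g$nodes))
  sigma <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sig <- numeric(n); sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nb[[v]]) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
            sig[w] <- sig[w] + sig[v]
          } else if (d[w] == d[v] + 1) {
            sig[w] <- sig[w] + sig[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sig
  }
  structure(list(dist = dist, sigma = sigma, order = g$nodes),
            class = "sp_census")
}

#' @rdname shortest_path_census
#' @param census An `sp_census`.
#' @param i Inner node label.
#' @return `paths_through()`: matrix `gamma_jk(i)` of geodesic counts
#'   through `i` (0 on rows/columns involving `i` itself).
#' @export
paths_through <- function(census, i) {
  stopifnot(inherits(census, "sp_census"))
  d <- census$dist; s <- census$sigma
  on_path <- outer(d[, i], d[i, ], `+`) == d
  on_path[is.na(on_path)] <- FALSE  # Inf + Inf == Inf comparisons
  thr <- outer(s[, i], s[i, ]) * on_path
  thr[i, ] <- 0; thr[, i] <- 0
  diag(thr) <- 0
  thr
}

#' Betweenness centrality
#'
#' `b_i = sum over unordered pairs {j, k} (j, k != i) of the fraction of
#' j-k geodesics that pass through i`; unnormalised, endpoints excluded.
#' Computed by Brandes' dependency-accumulation algorithm (via
#' \pkg{igraph}); the package's own path census provides the brute-force
#' cross-check used in the test-suite.
#'
#' @inheritParams contribution_centrality
#' @return A `centrality_result`.
#' @export
betweenness_centrality <- function(data) {
  g <- as_netgraph(data)
  b <- igraph::betweenness(as_igraph(g), directed = FALSE, weights = NA)
  new_centrality_result(b[g$nodes], method = "betweenness", g = g)
}

#' Closeness centrality
#'
#' The inverse mean geodesic distance, `c_i = (N_c - 1) / sum_j d(i, j)`
#' with the sum over the connected component of `i` (size `N_c`):
#' closeness is calculated separately for each connected component, and a
#' singleton component scores 0 with a warning.
#'
#' @inheritParams contribution_centrality
#' @return A `centrality_result`.
#' @export
closeness_centrality <- function(data) {
  g <- as_netgraph(data)
  cen <- shortest_path_census(g)
  memb <- component_membership(g)
  scores <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  for (comp in unique(memb)) {
    sel <- which(memb == comp)
    if (length(sel) == 1L) {
      warning("singleton component (node '", g$nodes[sel],
              "') assigned closeness 0", call. = FALSE)
      next
    }
    dsub <- cen$dist[sel, sel, drop = FALSE]
    scores[sel] <- (length(sel) - 1) / rowSums(dsub)
  }
  new_centrality_result(scores, method = "closeness", g = g)
}

#' Information centrality
#'
#' Stephenson-Zelen information centrality: the information of the
#' combined paths between `i` and `j` is
#' `I_ij = 1 / (C_ii + C_jj - 2 C_ij)` with `C` the inverse of the
#' Laplacian plus the all-ones matrix, and the score of `i` is the
#' harmonic mean of `I_ij` over all other nodes `j`:
#' `score_i = (N - 1) / sum_{j != i} 1 / I_ij`.  Disconnected graphs are
#' handled per component; singleton components score 0 with a warning.
#'
#' @inheritParams contribution_centrality
#' @return A `centrality_result`.
#' @export
information_centrality <- function(data) {
  g <- as_netgraph(data)
  A <- adjacency_matrix(g, sparse = FALSE, weighted = FALSE)
  memb <- component_membership(g)
  scores <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  for (comp in unique(memb)) {
    sel <- which(memb == comp)
    nc <- length(sel)
    if (nc == 1L) {
      warning("singleton component (node '", g$nodes[sel],
              "') assigned information centrality 0", call. = FALSE)
      next
    }
    Asub <- A[sel, sel, drop = FALSE]
    L <- diag(rowSums(Asub)) - Asub
    C <- solve(L + matrix(1, nc, nc))
    cd <- diag(C)
    # sum_{j != i} (C_ii + C_jj - 2 C_ij)
    denom <- (nc - 1) * cd + (sum(cd) - cd) - 2 * (rowSums(C) - cd)
    scores[sel] <- (nc - 1) / denom
  }
  new_centrality_result(scores, method = "information", g = g)
}

#' Communicability (subgraph) centrality
#'
#' Weighs every closed walk starting and ending at a node by the inverse
#' factorial of its length: `score_i = (exp(A))_ii`, the diagonal of the
#' matrix exponential of the adjacency matrix, computed through the
#' symmetric eigendecomposition `sum_k exp(lambda_k) u_ik^2`.  Always
#' at least 1 (the length-0 walk).
#'
#' @inheritParams contribution_centrality
#' @return A `centrality_result`.
#' @export
communicability_centrality <- function(data) {
  g <- as_netgraph(data)
  A <- adjacency_matrix(g, sparse = FALSE, weighted = FALSE)
  eg <- eigen(A, symmetric = TRUE)
  scores <- as.numeric((eg$vectors^2) %*% exp(eg$values))
  new_centrality_result(stats::setNames(scores, g$nodes),
                        method = "communicability", g = g)
}

#' Compute any centrality by name
#'
#' Uniform dispatcher over the seven measures, used by the comparison
#' table and the command-line interface.
#'
#' @inheritParams contribution_centrality
#' @param method One of `"contribution"`, `"degree"`, `"eigenvector"`,
#'   `"betweenness"`, `"closeness"`, `"information"`,
#'   `"communicability"`.
#' @param ... Passed to the underlying measure (e.g. `measure`,
#'   `convention`, `tol` for `"contribution"`).
#' @return A `centrality_result`.
#' @export
centrality <- function(data, method = c("contribution", "degree",
                                        "eigenvector", "betweenness",
                                        "closeness", "information",
                                        "communicability"), ...) {
  method <- match.arg(method)
  fn <- switch(method,
    contribution = contribution_centrality,
    degree = degree_centrality,
    eigenvector = eigenvector_centrality,
    betweenness = betweenness_centrality,
    closeness = closeness_centrality,
    information = information_centrality,
    communicability = communicability_centrality
  )
  fn(data, ...)
}
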