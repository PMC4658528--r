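#' Dominant eigenpair of a symmetric nonnegative matrix
#'
#' Shifted power iteration computing the Perron eigenpair: the largest
#' eigenvalue and its nonnegative unit eigenvector.  Iterating on
#' `M + sigma I` with a small positive shift (`sigma` = a quarter of the
#' largest row sum) guarantees convergence also for bipartite-type
#' spectra where `-lambda_max` is an eigenvalue; the reported eigenvalue
#' is the Rayleigh quotient of the unshifted matrix.  The start vector is
#' the fixed uniform positive vector, so results are deterministic.
#'
#' @param M Square symmetric entrywise-nonnegative matrix (base matrix or
#'   \pkg{Matrix}), not all zero.
#' @param tol Convergence tolerance on the relative residual
#'   `||Mv - lambda v|| / lambda`.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   diagnostics.
#' @return List with `value` (lambda >= 0), `vector` (unit Euclidean
#'   norm, entrywise >= 0, named when `M` has dimnames), `iterations`,
#'   `residual`, `converged`.
#' @examples
#' A <- adjacency_matrix(data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1)))
#' dominant_eigenpair(A)$value  # cycle C4: lambda = 2
#' @export
dominant_eigenpair <- function(M, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(M)
  stopifnot(n == ncol(M), n >= 1L)
  asym <- max(abs(M - Matrix::t(M)))
  if (asym > 1e-12 * max(1, max(abs(M)))) {
    stop("matrix is not symmetric (max asymmetry ", format(asym), ")",
         call. = FALSE)
  }
  if (min(M) < 0) {
    stop("matrix has negative entries; the Perron-Frobenius argument needs ",
         "a nonnegative matrix", call. = FALSE)
  }
  rs <- Matrix::rowSums(M)
  if (max(rs) == 0) {
    stop("degenerate weight matrix: all entries are zero, no dominant ",
         "eigenvector exists (this happens e.g. for complete graphs under ",
         "the closed Jaccard convention)", call. = FALSE)
  }
  sigma <- max(rs) / 4
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  res <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    Mv <- as.numeric(M %*% v)
    lam <- sum(v * Mv)
    res <- sqrt(sum((Mv - lam * v)^2)) / max(lam, .Machine$double.xmin)
    if (res <= tol) break
    w <- Mv + sigma * v
    v <- w / sqrt(sum(w^2))
  }
  if (res > tol) {
    stop("power iteration did not converge in ", max_iter,
         " iterations (residual ", format(res), ")", call. = FALSE)
  }
  # fix sign, clamp roundoff negatives; a real negative entry is a defect
  k <- which.max(abs(v))
  if (v[k] < 0) v <- -v
  if (any(v < -tol)) {
    stop("dominant eigenvector has negative entries beyond tolerance; ",
         "matrix violates the method's assumptions", call. = FALSE)
  }
  v[v < 0] <- 0
  v <- v / sqrt(sum(v^2))
  names(v) <- rownames(M)
  list(value = lam, vector = v, iterations = it, residual = res,
       converged = TRUE)
}

#' Irreducibility of a weight matrix
#'
#' A symmetric nonnegative matrix is irreducible exactly when the graph
#' of its nonzero entries is connected; irreducibility is what makes the
#' Perron eigenvector unique and strictly positive.  `W` can be reducible
#' even when the underlying graph is connected, because edges with zero
#' dissimilarity drop out of `W`.
#'
#' @param W A `weight_matrix` (or any symmetric matrix).
#' @return List with `irreducible` (flag) and `components` (tibble
#'   `node`, `component` of the nonzero-support graph).
#' @export
check_irreducibility <- function(W) {
  M <- if (inherits(W, "weight_matrix")) W$values else W
  memb <- pattern_membership(M)
  nodes <- rownames(M) %||% as.character(seq_len(nrow(M)))
  list(
    irreducible = length(unique(memb)) == 1L,
    components = tibble::tibble(node = nodes, component = unname(memb))
  )
}

# ---- centrality result container ---------------------------------------

new_centrality_result <- function(scores, method, g, measure = NA_character_,
                                  convention = NA_character_,
                                  eigenvalue = NA_real_, converged = NA,
                                  iterations = NA_integer_,
                                  residual = NA_real_, tol = NA_real_,
                                  components = NULL) {
  structure(
    list(
      scores = tibble::tibble(node = names(scores), score = unname(scores)),
      method = method, measure = measure, convention = convention,
      eigenvalue = eigenvalue, converged = converged,
      iterations = iterations, residual = residual, tol = tol,
      components = components,
      n_nodes = length(g$nodes), n_edges = nrow(g$edges)
    ),
    class = "centrality_result"
  )
}

#' @export
print.centrality_result <- function(x, ...) {
  cat("<centrality_result> method = ", x$method, sep = "")
  if (!is.na(x$measure)) {
    cat(" (measure = ", x$measure, ", convention = ", x$convention, ")",
        sep = "")
  }
  cat("\n  ", x$n_nodes, " nodes, ", x$n_edges, " edges", sep = "")
  if (!is.na(x$eigenvalue)) {
    cat(", lambda_max = ", format(x$eigenvalue, digits = 6), sep = "")
  }
  cat("\nTop nodes:\n")
  print(utils::head(rank_centrality(x), 5L))
  invisible(x)
}

# run a spectral centrality per connected component of g on matrix M
# (rows/cols in g's node order); scores get unit norm within components.
spectral_scores <- function(M, g, tol, max_iter, method_label) {
  memb <- component_membership(g)
  comps <- sort(unique(memb))
  if (length(comps) > 1L) {
    warning("graph is disconnected (", length(comps), " components); ",
            method_label, " computed separately per component -- scores are ",
            "only comparable within a component", call. = FALSE)
  }
  scores <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  diag_rows <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    sel <- which(memb == comps[ci])
    if (length(sel) == 1L) {
      warning("singleton component (node '", g$nodes[sel],
              "') assigned score 0", call. = FALSE)
      diag_rows[[ci]] <- tibble::tibble(
        component = comps[ci], size = 1L, eigenvalue = NA_real_,
        iterations = NA_integer_, residual = NA_real_
      )
      next
    }
    sub <- M[sel, sel, drop = FALSE]
    ep <- dominant_eigenpair(sub, tol = tol, max_iter = max_iter)
    scores[sel] <- ep$vector
    diag_rows[[ci]] <- tibble::tibble(
      component = comps[ci], size = length(sel), eigenvalue = ep$value,
      iterations = ep$iterations, residual = ep$residual
    )
  }
  list(scores = scores, components = dplyr::bind_rows(diag_rows))
}

#' Contribution centrality
#'
#' The package's core method: eigenvector centrality in which each
#' neighbour's contribution is weighted by how structurally dissimilar
#' the neighbour is.  Scores are the dominant (Perron) eigenvector of
#' `W = A o D`, the entrywise product of the adjacency matrix `A` and the
#' pairwise neighbourhood-dissimilarity matrix `D`.  A neighbour that
#' duplicates a node's own neighbourhood contributes little; a neighbour
#' that bridges to otherwise unreachable parts of the network contributes
#' a lot.  The method has no tunable parameter.
#'
#' For triangle-free graphs under the open convention every edge has
#' dissimilarity 1, `W` equals `A`, and the method coincides with plain
#' eigenvector centrality.
#'
#' @inheritParams dissimilarity_matrix
#' @inheritParams dominant_eigenpair
#' @param data A graph: a [netgraph()] or an edge data frame (first two
#'   columns endpoints, optional `weight`).
#' @return A `centrality_result`; use [tidy()][generics::tidy] /
#'   [rank_centrality()] for the ranked score table, [glance()] for the
#'   fit summary.  Scores are unit-Euclidean-normalised and nonnegative.
#'   On a disconnected graph the computation runs per component with a
#'   warning (scores are comparable only within a component).  If `W` is
#'   reducible despite a connected graph (zero-dissimilarity edges), a
#'   warning reports it and the Perron vector may contain zeros.
#' @examples
#' res <- contribution_centrality(load_fixture("florentine"))
#' head(tidy(res), 3)
#' @export
contribution_centrality <- function(data, measure = "jaccard",
                                    convention = c("closed", "open"),
                                    tol = 1e-10, max_iter = 10000L) {
  g <- as_netgraph(data)
  convention <- match.arg(convention)
  if (length(g$nodes) == 0L) stop("empty graph", call. = FALSE)
  weighted <- measure == "tanimoto" && is_weighted(g)
  A <- adjacency_matrix(g, weighted = weighted)
  D <- dissimilarity_matrix(g, measure = measure, convention = convention)
  W <- contribution_weight_matrix(A, D)
  memb <- component_membership(g)
  if (length(unique(memb)) == 1L && length(g$nodes) > 1L &&
      Matrix::nnzero(W$values) > 0) {
    irr <- check_irreducibility(W)
    if (!irr$irreducible) {
      warning("weight matrix W is reducible although the graph is connected ",
              "(some edges have zero dissimilarity); the dominant ",
              "eigenvector need not be unique and may contain zero entries",
              call. = FALSE)
    }
  }
  sp <- spectral_scores(W$values, g, tol, max_iter, "contribution centrality")
  res <- new_centrality_result(
    sp$scores, method = "contribution", g = g, measure = measure,
    convention = convention,
    eigenvalue = max_or_na(sp$components$eigenvalue),
    converged = TRUE,
    iterations = max(sp$components$iterations, 0L, na.rm = TRUE),
    residual = max_or_na(sp$components$residual), tol = tol,
    components = sp$components
  )
  res$n_zero_scores <- sum(sp$scores == 0)
  res
}
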