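# registry of pairwise dissimilarity measures
the_measures <- new.env(parent = emptyenv())

#' Jaccard dissimilarity between two nodes' neighbourhoods
#'
#' `d(i, j) = 1 - |eta(i) n eta(j)| / |eta(i) u eta(j)|`: 0 when the two
#' neighbourhoods are identical, 1 when they are disjoint.  The
#' neighbourhood map fixes the convention: under `open` a node is not in
#' its own neighbourhood, under `closed` it is (see [neighborhoods()]).
#'
#' @param nm A neighbourhood map from [neighborhoods()].
#' @param i,j Node labels present in `nm`.
#' @return A number in `[0, 1]`.  Two nodes with empty neighbourhoods
#'   (isolated pair, open convention) give 0 with a warning: vacuously
#'   identical neighbourhoods.
#' @examples
#' nm <- neighborhoods(data.frame(from = c("a", "b"), to = c("b", "c")))
#' jaccard_dissimilarity(nm, "a", "c")  # same neighbourhood {b} -> 0
#' @export
jaccard_dissimilarity <- function(nm, i, j) {
  a <- nm[[i]]; b <- nm[[j]]
  if (is.null(a) || is.null(b)) {
    stop("node not present in the neighbourhood map", call. = FALSE)
  }
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both neighbourhoods empty for pair ('", i, "', '", j,
            "'); dissimilarity defined as 0", call. = FALSE)
    return(0)
  }
  1 - length(intersect(a, b)) / u
}

#' Tanimoto dissimilarity between two nodes' adjacency rows
#'
#' The weighted-network generalisation of Jaccard dissimilarity:
#' `d(i, j) = 1 - (ri . rj) / (|ri|^2 + |rj|^2 - ri . rj)` on rows `ri`,
#' `rj` of the (weighted) adjacency matrix.  On a 0/1 adjacency it equals
#' the Jaccard dissimilarity of open neighbourhoods exactly.  Weights
#' must be positive so that the resulting weight matrix stays
#' nonnegative, the method's Perron-Frobenius precondition.
#'
#' @param g A graph; edge weights are used when present.
#' @param i,j Node labels.
#' @return A number in `[0, 1]` (0 for identical rows; both-zero rows
#'   give 0 with a warning, mirroring [jaccard_dissimilarity()]).
#' @export
tanimoto_dissimilarity <- function(g, i, j) {
  g <- as_netgraph(g)
  A <- adjacency_matrix(g)
  if (!(i %in% g$nodes) || !(j %in% g$nodes)) {
    stop("node not present in the graph", call. = FALSE)
  }
  tanimoto_from_rows(as.numeric(A[i, ]), as.numeric(A[j, ]), i, j)
}

tanimoto_from_rows <- function(ri, rj, i = "?", j = "?") {
  dot <- sum(ri * rj)
  den <- sum(ri^2) + sum(rj^2) - dot
  if (den == 0) {
    warning("both adjacency rows zero for pair ('", i, "', '", j,
            "'); dissimilarity defined as 0", call. = FALSE)
    return(0)
  }
  1 - dot / den
}

#' Register a custom dissimilarity measure
#'
#' Extends [dissimilarity_matrix()] (and every function built on it, in
#' particular [contribution_centrality()]) with a user-defined pairwise
#' structural dissimilarity.  The function is called per node pair and
#' its output is range-checked into `[0, 1]` at evaluation time -- an
#' out-of-range value is an error naming the offending pair, never
#' silently clamped, because nonnegativity of the weight matrix is the
#' method's mathematical precondition.
#'
#' @param name New measure name (must not collide with an existing one).
#' @param fn `function(i, j, nm, g)` returning a single number in
#'   `[0, 1]`; `nm` is the neighbourhood map under the convention in
#'   force, `g` the graph.
#' @return `name`, invisibly.
#' @examples
#' register_measure("const_half", function(i, j, nm, g) 0.5)
#' list_measures()
#' @export
register_measure <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (name %in% list_measures()) {
    stop("a measure named '", name, "' is already registered", call. = FALSE)
  }
  assign(name, fn, envir = the_measures)
  invisible(name)
}

#' @rdname register_measure
#' @export
list_measures <- function() {
  sort(c("jaccard", "tanimoto", ls(the_measures)))
}

# test/teardown helper (not part of the public surface)
deregister_measure <- function(name) {
  if (exists(name, envir = the_measures, inherits = FALSE)) {
    rm(list = name, envir = the_measures)
  }
  invisible(name)
}

#' Dissimilarity matrix of a graph
#'
#' Assembles the symmetric matrix `D` with entries `d_ij` given by the
#' chosen pairwise measure.  In sparse mode (the default) `d_ij` is
#' evaluated only for adjacent pairs -- the only entries that survive the
#' entrywise product with the adjacency matrix -- which keeps large
#' graphs cheap; dense mode materialises all pairs for diagnostics.
#'
#' @inheritParams adjacency_matrix
#' @param measure `"jaccard"`, `"tanimoto"`, or a name registered with
#'   [register_measure()].
#' @param convention Neighbourhood convention, `"closed"` (default; the
#'   convention that reproduces the canonical benchmark rankings, see the
#'   package vignette) or `"open"`.
#' @param sparse Evaluate adjacent pairs only?
#' @return An object of class `dissim_matrix`: list with `values`
#'   (symmetric matrix, zero diagonal, entries in `[0, 1]`), `order`
#'   (node labels), `measure` and `convention`.
#' @examples
#' tri <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))
#' dissimilarity_matrix(tri, convention = "open")$values
#' @export
dissimilarity_matrix <- function(g, measure = "jaccard",
                                 convention = c("closed", "open"),
                                 sparse = TRUE) {
  g <- as_netgraph(g)
  convention <- match.arg(convention)
  if (!measure %in% list_measures()) {
    stop("unknown dissimilarity measure '", measure, "'; see list_measures()",
         call. = FALSE)
  }
  n <- length(g$nodes)
  pairs <- if (sparse) {
    edge_indices(g)
  } else {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  }
  d <- pair_dissimilarities(g, pairs, measure, convention)
  values <- Matrix::sparseMatrix(
    i = c(pairs[, 1L], pairs[, 2L]), j = c(pairs[, 2L], pairs[, 1L]),
    x = c(d, d), dims = c(n, n), dimnames = list(g$nodes, g$nodes)
  )
  if (!sparse) values <- as.matrix(values)
  structure(
    list(values = values, order = g$nodes, measure = measure,
         convention = convention),
    class = "dissim_matrix"
  )
}

# vectorised-by-edge evaluation of a measure over index pairs
pair_dissimilarities <- function(g, pairs, measure, convention) {
  if (nrow(pairs) == 0L) return(numeric())
  if (measure == "jaccard") {
    nb <- neighbor_index_list(g, closed = convention == "closed")
    sizes <- lengths(nb)
    d <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      common <- length(intersect(nb[[i]], nb[[j]]))
      u <- sizes[[i]] + sizes[[j]] - common
      d[k] <- if (u == 0L) 0 else 1 - common / u
    }
    return(d)
  }
  if (measure == "tanimoto") {
    A <- adjacency_matrix(g, sparse = FALSE)
    d <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      d[k] <- suppressWarnings(tanimoto_from_rows(A[i, ], A[j, ]))
    }
    return(d)
  }
  fn <- get(measure, envir = the_measures)
  nm <- neighborhoods(g, convention)
  d <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- g$nodes[pairs[k, 1L]]; j <- g$nodes[pairs[k, 2L]]
    val <- fn(i, j, nm, g)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val < 0 || val > 1) {
      stop("measure '", measure, "' returned ", deparse(val), " for pair ('",
           i, "', '", j, "'); dissimilarities must lie in [0, 1]",
           call. = FALSE)
    }
    d[k] <- val
  }
  d
}

#' Contribution weight matrix W = A o D
#'
#' The entrywise (Hadamard) product of the adjacency matrix and a
#' dissimilarity matrix.  `W` is symmetric, nonnegative, has zero
#' diagonal and support contained in the support of `A`; its dominant
#' eigenvector is the contribution centrality.  Edges whose endpoints
#' have identical neighbourhoods (`d = 0`) drop out of `W`, so `W` can be
#' sparser than `A`.
#'
#' @param A Adjacency matrix with node labels as dimnames (from
#'   [adjacency_matrix()]).
#' @param D A `dissim_matrix` from [dissimilarity_matrix()] (or a bare
#'   matrix with matching dimnames).
#' @return An object of class `weight_matrix`: list with `values`,
#'   `order`, `measure`, `convention`.
#' @examples
#' tri <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))
#' A <- adjacency_matrix(tri)
#' W <- contribution_weight_matrix(A, dissimilarity_matrix(tri, convention = "open"))
#' as.matrix(W$values)  # (2/3) * A
#' @export
contribution_weight_matrix <- function(A, D) {
  Dvals <- if (inherits(D, "dissim_matrix")) D$values else D
  ord <- rownames(A)
  if (is.null(ord) || !identical(ord, rownames(Dvals))) {
    stop("A and D must carry the same node order in their dimnames",
         call. = FALSE)
  }
  W <- A * Dvals
  W <- Matrix::drop0(methods::as(W, "CsparseMatrix"))
  structure(
    list(values = W, order = ord,
         measure = if (inherits(D, "dissim_matrix")) D$measure else NA_character_,
         convention = if (inherits(D, "dissim_matrix")) D$convention else NA_character_),
    class = "weight_matrix"
  )
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat("<dissim_matrix> ", length(x$order), " nodes, measure = ", x$measure,
      ", convention = ", x$convention, "\n", sep = "")
  invisible(x)
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("<weight_matrix> ", length(x$order), " nodes, ",
      Matrix::nnzero(x$values) / 2, " weighted edges (measure = ", x$measure,
      ", convention = ", x$convention, ")\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.dissim_matrix <- function(x, ...) as.matrix(x$values)

#' @export
as.matrix.weight_matrix <- function(x, ...) as.matrix(x$values)

#' Export a dissimilarity or weight matrix as MatrixMarket
#'
#' Diagnostic export of the sparse `D` or `W` matrix in MatrixMarket
#' coordinate format, readable by any sparse linear-algebra stack.  A
#' comment line records the node order.
#'
#' @param x A `dissim_matrix` or `weight_matrix`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_matrix_market <- function(x, file) {
  stopifnot(inherits(x, c("dissim_matrix", "weight_matrix")))
  M <- methods::as(x$values, "CsparseMatrix")
  Matrix::writeMM(M, file)
  invisible(file)
}
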