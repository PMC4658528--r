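#' Build an undirected simple graph from an edge table
#'
#' A `netgraph` is the universal input object of the package: an undirected
#' simple graph (no self-loops, no parallel edges) with character node
#' labels in stable first-appearance order.  All matrices derived from it
#' carry this ordering in their dimnames, so results are addressed by
#' label, never by index.
#'
#' @param edges A data frame whose first two columns are edge endpoints
#'   (coerced to character).  An optional `weight` column (or third
#'   numeric column) holds positive edge weights.  `NULL` gives an
#'   edgeless graph.
#' @param nodes Optional character vector of node labels.  Labels not
#'   appearing in `edges` become isolated nodes; labels that do appear are
#'   kept in first-appearance order, followed by the extra labels.
#'
#' @return An object of class `netgraph`: a list with elements `nodes`
#'   (character vector) and `edges` (a tibble with columns `from`, `to`
#'   and, for weighted graphs, `weight`).
#'
#' @details Repeated edge lines collapse to a single edge with a warning
#'   (the first weight is kept); self-loops are an error.
#'
#' @examples
#' g <- netgraph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' g$nodes
#' @export
netgraph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    return(new_netgraph(
      nodes = as.character(nodes %||% character()),
      edges = tibble::tibble(from = character(), to = character())
    ))
  }
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) {
    stop("`edges` needs at least two columns (endpoints)", call. = FALSE)
  }
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  weight <- NULL
  if ("weight" %in% names(edges)[-(1:2)]) {
    weight <- as.numeric(edges[["weight"]])
  } else if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) {
    weight <- as.numeric(edges[[3L]])
  }
  build_netgraph(from, to, weight, extra_nodes = as.character(nodes %||% character()))
}

new_netgraph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "netgraph")
}

# shared validating constructor: dedup, self-loop check, node ordering
build_netgraph <- function(from, to, weight = NULL, extra_nodes = character(),
                           where = NULL) {
  loc <- function(i) if (is.null(where)) paste0("edge ", i) else
    paste0("line ", where[i])
  bad <- is.na(from) | is.na(to) | from == "" | to == ""
  if (any(bad)) {
    stop("missing endpoint label at ", loc(which(bad)[1L]), call. = FALSE)
  }
  self <- from == to
  if (any(self)) {
    stop("self-loop at ", loc(which(self)[1L]), " (node '",
         from[which(self)[1L]], "')", call. = FALSE)
  }
  if (!is.null(weight)) {
    wbad <- is.na(weight) | weight <= 0
    if (any(wbad)) {
      stop("edge weight must be a positive real at ", loc(which(wbad)[1L]),
           call. = FALSE)
    }
  }
  nodes <- unique(c(as.vector(rbind(from, to)), extra_nodes))
  i <- match(from, nodes)
  j <- match(to, nodes)
  key <- paste0(pmin(i, j), "-", pmax(i, j))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed; first occurrence kept",
            call. = FALSE)
    from <- from[!dup]; to <- to[!dup]
    if (!is.null(weight)) weight <- weight[!dup]
  }
  edges <- tibble::tibble(from = from, to = to)
  if (!is.null(weight)) edges$weight <- weight
  new_netgraph(nodes = nodes, edges = edges)
}

#' @export
print.netgraph <- function(x, ...) {
  cat("<netgraph> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (is_weighted(x)) " (weighted)", "\n", sep = "")
  invisible(x)
}

#' Coerce to a netgraph
#'
#' Edge tables (data frames / tibbles) and `netgraph` objects are accepted
#' everywhere a graph is expected; this generic performs the coercion.
#'
#' @param x A `netgraph`, or a data frame of edges as in [netgraph()].
#' @param ... Passed on to methods.
#' @return A `netgraph`.
#' @export
as_netgraph <- function(x, ...) UseMethod("as_netgraph")

#' @export
as_netgraph.netgraph <- function(x, ...) x

#' @export
as_netgraph.data.frame <- function(x, ...) netgraph(x, ...)

#' @export
as_netgraph.default <- function(x, ...) {
  stop("cannot interpret an object of class <", paste(class(x), collapse = "/"),
       "> as a graph; supply a netgraph or an edge data frame", call. = FALSE)
}

#' @rdname as_netgraph
#' @export
is_weighted <- function(x) "weight" %in% names(as_netgraph(x)$edges)

# integer endpoint indices, one row per edge
edge_indices <- function(g) {
  cbind(match(g$edges$from, g$nodes), match(g$edges$to, g$nodes))
}

#' Read a whitespace-delimited edge list
#'
#' Each non-comment line is `<u> <v>` or, with `weighted = TRUE`,
#' `<u> <v> <w>` with `w` a positive real.  Text from the first `#` on a
#' line is a comment.  Fields are separated by arbitrary whitespace.
#'
#' @param file Path to a file, a connection, or a character vector of
#'   lines (anything [base::readLines()] accepts, plus literal text).
#' @param weighted Expect (and keep) a third weight column?
#' @return A [netgraph()].
#' @export
read_edge_list <- function(file, weighted = FALSE) {
  lines <- if (is.character(file) && length(file) == 1L && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else if (inherits(file, "connection")) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
  lines <- sub("#.*$", "", lines)
  keep <- which(!grepl("^\\s*$", lines))
  if (length(keep) == 0L) return(netgraph())
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  want <- if (weighted) 3L else 2L
  bad <- nf != want
  if (any(bad)) {
    k <- which(bad)[1L]
    stop("line ", keep[k], ": expected ", want, " fields, found ", nf[k],
         call. = FALSE)
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  weight <- NULL
  if (weighted) {
    wtxt <- vapply(fields, `[[`, "", 3L)
    weight <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(weight)) {
      k <- which(is.na(weight))[1L]
      stop("line ", keep[k], ": weight '", wtxt[k], "' is not a number",
           call. = FALSE)
    }
  }
  build_netgraph(from, to, weight, where = keep)
}

#' Read a graph from a GML file
#'
#' Reads the minimal GML dialect
#' `graph [ node [ id label ] edge [ source target value ] ]` (parsing is
#' delegated to \pkg{igraph}).  Node labels come from the `label`
#' attribute when present, otherwise from `id`.  An edge `value`
#' attribute is kept as the edge weight unless `topology_only = TRUE`,
#' which keeps only the unweighted structure.
#'
#' @param file Path to a GML file.
#' @param topology_only Drop edge weights and keep only the topology?
#' @return A [netgraph()].
#' @export
read_gml <- function(file, topology_only = FALSE) {
  ig <- igraph::read_graph(file, format = "gml")
  labels <- igraph::vertex_attr(ig, "label")
  if (is.null(labels)) labels <- igraph::vertex_attr(ig, "id")
  if (is.null(labels)) labels <- seq_len(igraph::vcount(ig))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate node labels in GML file", call. = FALSE)
  }
  el <- igraph::as_edgelist(ig, names = FALSE)
  weight <- NULL
  if (!topology_only) {
    weight <- igraph::edge_attr(ig, "value")
    if (is.null(weight)) weight <- igraph::edge_attr(ig, "weight")
  }
  build_netgraph(labels[el[, 1L]], labels[el[, 2L]], weight,
                 extra_nodes = labels)
}

#' Adjacency matrix of a graph
#'
#' @param g A graph ([netgraph()] or edge data frame).
#' @param sparse Return a sparse \pkg{Matrix} (default) or a dense base
#'   matrix?
#' @param weighted Use edge weights when present?  With `FALSE` the
#'   matrix is binary 0/1.
#' @return A symmetric matrix with zero diagonal whose dimnames are the
#'   node labels in graph order.
#' @examples
#' adjacency_matrix(data.frame(from = c("a", "b"), to = c("b", "c")),
#'                  sparse = FALSE)
#' @export
adjacency_matrix <- function(g, sparse = TRUE, weighted = is_weighted(g)) {
  g <- as_netgraph(g)
  n <- length(g$nodes)
  dn <- list(g$nodes, g$nodes)
  ij <- edge_indices(g)
  x <- if (weighted && is_weighted(g)) g$edges$weight else rep(1, nrow(ij))
  A <- Matrix::sparseMatrix(
    i = c(ij[, 1L], ij[, 2L]), j = c(ij[, 2L], ij[, 1L]), x = c(x, x),
    dims = c(n, n), dimnames = dn
  )
  if (sparse) A else as.matrix(A)
}

#' Node neighbourhoods
#'
#' Returns the neighbourhood map eta(i) used by the dissimilarity
#' measures.  Under the `open` convention eta(i) is the set of neighbours
#' of `i` (excluding `i` itself); under `closed` the node is included in
#' its own neighbourhood.
#'
#' @inheritParams adjacency_matrix
#' @param convention `"open"` or `"closed"`.
#' @return A named list of character vectors, one entry per node, with
#'   attribute `convention`.
#' @export
neighborhoods <- function(g, convention = c("open", "closed")) {
  g <- as_netgraph(g)
  convention <- match.arg(convention)
  idx <- neighbor_index_list(g, closed = convention == "closed")
  out <- lapply(idx, function(k) g$nodes[k])
  attr(out, "convention") <- convention
  out
}

# integer adjacency lists; closed = TRUE appends the node itself
neighbor_index_list <- function(g, closed = FALSE) {
  n <- length(g$nodes)
  ij <- edge_indices(g)
  nb <- split(c(ij[, 2L], ij[, 1L]),
              factor(c(ij[, 1L], ij[, 2L]), levels = seq_len(n)))
  nb <- lapply(nb, as.integer)
  if (closed) nb <- lapply(seq_len(n), function(i) c(nb[[i]], i))
  names(nb) <- g$nodes
  nb
}

#' Connected components
#'
#' Breadth-first partition of the nodes into connected components.
#' Components are numbered in order of their first node in graph order,
#' so the result is deterministic.
#'
#' @inheritParams adjacency_matrix
#' @return A tibble with columns `node` and `component` (integer id).
#' @export
graph_components <- function(g) {
  g <- as_netgraph(g)
  memb <- component_membership(g)
  tibble::tibble(node = g$nodes, component = unname(memb))
}

component_membership <- function(g) {
  n <- length(g$nodes)
  nb <- neighbor_index_list(g)
  memb <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (memb[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    memb[s] <- comp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nb[[v]]) {
        if (memb[w] == 0L) {
          memb[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  names(memb) <- g$nodes
  memb
}

# components of an arbitrary symmetric nonzero pattern (matrix or Matrix)
pattern_membership <- function(M) {
  n <- nrow(M)
  P <- methods::as(methods::as(M != 0, "generalMatrix"), "TsparseMatrix")
  ii <- P@i + 1L; jj <- P@j + 1L
  keep <- ii != jj
  g <- new_netgraph(
    nodes = as.character(seq_len(n)),
    edges = tibble::tibble(from = as.character(ii[keep]),
                           to = as.character(jj[keep]))
  )
  # parallel entries (i,j)/(j,i) are harmless here: collapse silently
  dup <- duplicated(paste0(pmin(g$edges$from, g$edges$to), "-",
                           pmax(g$edges$from, g$edges$to)))
  g$edges <- g$edges[!dup, ]
  memb <- component_membership(g)[as.character(seq_len(n))]
  names(memb) <- rownames(M)
  memb
}

#' Generate a Barabasi-Albert scale-free graph
#'
#' Preferential-attachment growth: starting from `m` isolated seed nodes,
#' each new node attaches to `m` distinct existing nodes chosen with
#' probability proportional to their current degree (the first arrival
#' attaches to all seed nodes).  The result has exactly `m * (n - m)`
#' edges and is connected.
#'
#' @param n Number of nodes (`n > m`).
#' @param m Edges added per new node (`m >= 1`).
#' @param seed Integer seed; the same seed reproduces the same graph.
#'   The caller's RNG state is left untouched.
#' @return A [netgraph()] with nodes labelled `"1" ... "n"`.
#' @examples
#' g <- sample_ba(50, 2, seed = 1)
#' nrow(g$edges)  # 2 * (50 - 2)
#' @export
sample_ba <- function(n, m, seed = NULL) {
  if (!(m >= 1 && n > m)) {
    stop("need n > m >= 1 (got n = ", n, ", m = ", m, ")", call. = FALSE)
  }
  n <- as.integer(n); m <- as.integer(m)
  with_preserved_rng(seed, {
    n_new <- n - m
    from <- integer(m * n_new)
    to <- integer(m * n_new)
    repeated <- integer(2L * m * n_new)
    n_rep <- 0L
    targets <- seq_len(m)
    pos <- 0L
    for (v in seq.int(m + 1L, n)) {
      from[pos + seq_len(m)] <- v
      to[pos + seq_len(m)] <- targets
      pos <- pos + m
      repeated[n_rep + seq_len(2L * m)] <- c(targets, rep.int(v, m))
      n_rep <- n_rep + 2L * m
      if (v == n) break
      ts <- integer(0)
      while (length(ts) < m) {
        cand <- repeated[sample.int(n_rep, 1L)]
        if (!cand %in% ts) ts <- c(ts, cand)
      }
      targets <- ts
    }
    build_netgraph(as.character(from), as.character(to),
                   extra_nodes = as.character(seq_len(n)))
  })
}

# run code under a temporary RNG seed, restoring the caller's stream
with_preserved_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bundled benchmark networks
#'
#' Three classical social networks are shipped as GML files and loaded as
#' unweighted graphs:
#' \describe{
#'   \item{`florentine`}{Padgett's Florentine marriage ties between
#'     Renaissance families; the 15-family connected component (the
#'     isolated Pucci family is omitted, since eigenvector-type measures
#'     need connectivity). 20 edges.}
#'   \item{`karate`}{Zachary's karate club friendship network, members
#'     labelled `"1"`-`"34"`, topology only. 78 edges.}
#'   \item{`lesmis`}{Knuth's Les Miserables chapter coappearance network,
#'     77 characters, topology only (coappearance counts ignored).
#'     254 edges.}
#' }
#' Files are integrity-checked against the bundled manifest (MD5) at load
#' time.
#'
#' @param name One of `"florentine"`, `"karate"`, `"lesmis"`.
#' @return `load_fixture()`: a [netgraph()].  `fixture_manifest()`: a
#'   tibble with columns `name`, `file`, `nodes`, `edges`, `source`,
#'   `md5`.
#' @examples
#' g <- load_fixture("karate")
#' length(g$nodes)
#' @export
load_fixture <- function(name = c("florentine", "karate", "lesmis")) {
  name <- match.arg(name)
  man <- fixture_manifest()
  row <- man[man$name == name, ]
  path <- system.file("extdata", row$file, package = "contricent",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, row$md5)) {
    stop("fixture '", name, "' failed its checksum; reinstall the package",
         call. = FALSE)
  }
  g <- read_gml(path, topology_only = TRUE)
  stopifnot(length(g$nodes) == row$nodes, nrow(g$edges) == row$edges)
  g
}

#' @rdname load_fixture
#' @export
fixture_manifest <- function() {
  path <- system.file("extdata", "manifest.json", package = "contricent",
                      mustWork = TRUE)
  tibble::as_tibble(jsonlite::fromJSON(path))
}

# igraph view of a netgraph (baseline algorithms, oracles)
as_igraph <- function(g) {
  g <- as_netgraph(g)
  igraph::graph_from_data_frame(
    as.data.frame(g$edges), directed = FALSE,
    vertices = data.frame(name = g$nodes)
  )
}
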