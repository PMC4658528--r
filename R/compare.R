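# Rankings, rank agreement, score distributions and the runtime benchmark.

# order labels numerically when they all look like integers, else
# C-locale lexicographically -- the package-wide tie rule
label_order <- function(labels) {
  if (all(grepl("^[0-9]+$", labels))) {
    order(as.numeric(labels))
  } else {
    order(labels, method = "radix")
  }
}

#' Rank nodes by centrality score
#'
#' Sorts scores from highest to lowest; ties are broken by node label
#' (numeric-aware when all labels are integers, else lexicographic) so
#' rankings are reproducible.
#'
#' @param result A `centrality_result`, or a data frame with columns
#'   `node` and `score`.
#' @return A tibble with columns `rank`, `node`, `score` (scores
#'   non-increasing, ranks `1..N`).  Attribute `fully_tied` flags the
#'   degenerate all-equal case; attribute `tie_rule` documents the rule.
#' @examples
#' rank_centrality(degree_centrality(load_fixture("florentine")))[1:3, ]
#' @export
rank_centrality <- function(result) {
  scores <- if (inherits(result, "centrality_result")) {
    result$scores
  } else {
    tibble::as_tibble(result)[, c("node", "score")]
  }
  ord <- order(-scores$score, label_order_rank(scores$node))
  out <- tibble::tibble(
    rank = seq_len(nrow(scores)),
    node = scores$node[ord],
    score = scores$score[ord]
  )
  attr(out, "fully_tied") <- nrow(out) > 1L &&
    max(out$score) == min(out$score)
  attr(out, "tie_rule") <- "label (numeric-aware)"
  out
}

# rank position of each label under the tie rule (usable as an order() key)
label_order_rank <- function(labels) {
  ord <- label_order(labels)
  pos <- integer(length(labels))
  pos[ord] <- seq_along(labels)
  pos
}

#' Top-k nodes of a ranking
#'
#' @param x A ranking from [rank_centrality()] or a `centrality_result`.
#' @param k How many nodes (`0 <= k <= N`).
#' @return Character vector of the first `k` node labels.
#' @export
top_nodes <- function(x, k) {
  r <- if (inherits(x, "centrality_result")) rank_centrality(x) else x
  if (k > nrow(r)) {
    stop("k = ", k, " exceeds the number of ranked nodes (", nrow(r), ")",
         call. = FALSE)
  }
  utils::head(r$node, k)
}

#' Kendall rank correlation between two centrality results
#'
#' Tie-adjusted (tau-b) Kendall correlation of the two score vectors over
#' the shared node set: +1 for identical orderings, -1 for exactly
#' reversed strict orderings.  Ties are frequent in centrality scores
#' (symmetric nodes), hence tau-b.
#'
#' @param r1,r2 `centrality_result`s or rankings/data frames with `node`
#'   and `score` columns, over the same node set.
#' @return A number in `[-1, 1]`.
#' @export
kendall_tau <- function(r1, r2) {
  s1 <- result_scores(r1)
  s2 <- result_scores(r2)
  if (!setequal(names(s1), names(s2))) {
    stop("the two results are over different node sets", call. = FALSE)
  }
  stats::cor(s1, s2[names(s1)], method = "kendall")
}

result_scores <- function(r) {
  df <- if (inherits(r, "centrality_result")) r$scores else tibble::as_tibble(r)
  stats::setNames(df$score, df$node)
}

#' Histogram of normalised centrality scores
#'
#' Scores are normalised by their maximum and binned over `[0, 1]`, the
#' tabular form of the score-distribution views used to contrast how
#' differently the measures spread their mass over a network.
#'
#' @param result A `centrality_result`.
#' @param bins Number of equal-width bins.
#' @return A tibble with columns `bin`, `lower`, `upper`, `count`;
#'   counts sum to the number of nodes.
#' @export
score_distribution <- function(result, bins = 10L) {
  s <- result_scores(result)
  mx <- max(s)
  x <- if (mx > 0) s / mx else s
  breaks <- seq(0, 1, length.out = bins + 1L)
  cut_idx <- findInterval(x, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  tibble::tibble(
    bin = seq_len(bins),
    lower = breaks[-(bins + 1L)],
    upper = breaks[-1L],
    count = tabulate(cut_idx, nbins = bins)
  )
}

#' Side-by-side comparison of centrality measures
#'
#' Computes several centrality measures on the same graph and assembles
#' the classic comparison table: top-k node lists side by side, plus the
#' pairwise Kendall tau-b rank-agreement matrix.
#'
#' @inheritParams contribution_centrality
#' @param methods Measures to include (see [centrality()]); `"all"`
#'   expands to all seven.
#' @param top Number of rows of the top-node table.
#' @param ... Passed to [contribution_centrality()] (e.g. `measure`,
#'   `convention`).
#' @return An object of class `centrality_comparison`: list with `top`
#'   (tibble, one column per measure), `tau` (tibble of pairwise
#'   correlations), `results` (named list of `centrality_result`s), `k`.
#' @examples
#' cmp <- compare_centralities(load_fixture("florentine"),
#'                             methods = c("contribution", "degree"), top = 3)
#' cmp$top
#' @export
compare_centralities <- function(data, methods = "all", top = 10L, ...) {
  g <- as_netgraph(data)
  all_methods <- c("contribution", "betweenness", "closeness",
                   "communicability", "degree", "eigenvector", "information")
  if (identical(methods, "all")) methods <- all_methods
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  top <- min(top, length(g$nodes))
  results <- stats::setNames(lapply(methods, function(m) {
    if (m == "contribution") centrality(g, m, ...) else centrality(g, m)
  }), methods)
  top_tbl <- tibble::as_tibble(
    c(list(index = seq_len(top)),
      lapply(results, function(r) top_nodes(r, top)))
  )
  pairs <- expand.grid(method1 = methods, method2 = methods,
                       stringsAsFactors = FALSE)
  pairs$tau <- purrr::map2_dbl(pairs$method1, pairs$method2,
                               ~ kendall_tau(results[[.x]], results[[.y]]))
  structure(
    list(top = top_tbl, tau = tibble::as_tibble(pairs), results = results,
         k = top),
    class = "centrality_comparison"
  )
}

#' @export
print.centrality_comparison <- function(x, ...) {
  cat("<centrality_comparison> top-", x$k, " nodes by ",
      length(x$results), " measures\n", sep = "")
  print(x$top)
  invisible(x)
}

#' Runtime benchmark on Barabasi-Albert graphs
#'
#' Times [contribution_centrality()] on scale-free preferential-
#' attachment graphs of growing size.  Wall-clock timings are
#' hardware-dependent and purely informational: the function warns (does
#' not fail) if mean runtime is not non-decreasing in `n`.
#'
#' @param n_values Graph sizes to benchmark.
#' @param m Edges per new node of the generator.
#' @param reps Independent graphs (and timed runs) per size.
#' @param seed Integer seed making the benchmarked graph set
#'   reproducible.
#' @param ... Passed to [contribution_centrality()].
#' @return A tibble with columns `n`, `mean_seconds`, `sd_seconds`.
#' @export
runtime_benchmark <- function(n_values, m = 2L, reps = 10L, seed = 1L, ...) {
  rows <- lapply(seq_along(n_values), function(k) {
    n <- n_values[[k]]
    secs <- vapply(seq_len(reps), function(r) {
      g <- sample_ba(n, m, seed = seed + 1000L * k + r)
      unname(system.time(contribution_centrality(g, ...))["elapsed"])
    }, numeric(1))
    tibble::tibble(n = n, mean_seconds = mean(secs),
                   sd_seconds = stats::sd(secs))
  })
  out <- dplyr::bind_rows(rows)
  if (is.unsorted(out$mean_seconds[order(out$n)])) {
    warning("mean runtime is not monotone in n (noisy timings are common ",
            "at small sizes)", call. = FALSE)
  }
  out
}
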