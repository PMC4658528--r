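#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a centrality result
#'
#' @param x A `centrality_result`.
#' @param ... Unused.
#' @return The ranked score table of [rank_centrality()]: a tibble with
#'   columns `rank`, `node`, `score`.
#' @export
tidy.centrality_result <- function(x, ...) rank_centrality(x)

#' One-row summary of a centrality result
#'
#' @param x A `centrality_result`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `measure`, `convention`,
#'   `n_nodes`, `n_edges`, `eigenvalue`, `converged`, `iterations`,
#'   `residual`.
#' @export
glance.centrality_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, measure = x$measure, convention = x$convention,
    n_nodes = x$n_nodes, n_edges = x$n_edges, eigenvalue = x$eigenvalue,
    converged = x$converged, iterations = x$iterations,
    residual = x$residual
  )
}

#' Tidy a centrality comparison
#'
#' @param x A `centrality_comparison`.
#' @param ... Unused.
#' @return A long tibble with columns `method`, `rank`, `node`, `score`
#'   covering the full rankings of every compared measure.
#' @export
tidy.centrality_comparison <- function(x, ...) {
  purrr::imap_dfr(x$results, function(r, m) {
    dplyr::mutate(rank_centrality(r), method = m, .before = 1L)
  })
}
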