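#' Weighted overlap graph over candidate clusters
#'
#' Builds the undirected graph whose vertices are the scored candidate
#' clusters (weights `w`) and whose edges join any two clusters sharing at
#' least one locus without being identical. Clusters with identical locus
#' sets would only create zero-information ties, so they are merged
#' beforehand, keeping the copy with the higher weight (ties by
#' lexicographically smaller `cluster_id`).
#'
#' @param scored Scored cluster tibble from [score_clusters()] (must carry
#'   strictly positive `w`).
#' @return An \pkg{igraph} graph with vertex attributes `name`
#'   (cluster id) and `weight`.
#' @export
build_overlap_graph <- function(scored) {
  stopifnot(all(c("cluster_id", "loci", "w") %in% names(scored)))
  if (any(scored$w <= 0)) abort("cluster weights must be strictly positive")

  sets <- purrr::map(scored$loci, ~ sort(unique(as.character(.x))))
  key <- purrr::map_chr(sets, ~ paste(.x, collapse = "\r"))
  ord <- order(-scored$w, scored$cluster_id)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  scored <- scored[keep, , drop = FALSE]
  sets <- sets[keep]

  n <- nrow(scored)
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (length(intersect(sets[[i]], sets[[j]])) > 0) {
          edges <- c(edges, i, j)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = scored$cluster_id)
  g <- igraph::set_vertex_attr(g, "weight", value = scored$w)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  g
}

#' Greedy maximum-weighted independent-set selection
#'
#' Iterates until the graph is empty: (i) find the connected components of
#' the current graph; (ii) in each component select the vertex maximising
#' `f(v) = w(v) / (deg(v) + 1)`; (iii) delete each selected vertex
#' together with its neighbours, storing the vertex in the output. The
#' result is an independent set whose total weight is at least
#' `sum_v w(v) / (deg(v) + 1)` on the input graph.
#'
#' Ties on `f` are broken by higher weight, then by lexicographically
#' smaller vertex name, so selection is deterministic.
#'
#' @param g An overlap graph from [build_overlap_graph()].
#' @return Character vector of selected cluster ids.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' g <- igraph::set_vertex_attr(g, "weight",
#'   value = c(1, 10, 1)[match(igraph::V(g)$name, c("a", "b", "c"))])
#' wmin_select(g)  # "b"
#' @export
wmin_select <- function(g) {
  w <- igraph::vertex_attr(g, "weight")
  if (is.null(w)) abort("graph has no vertex `weight` attribute")
  if (any(w <= 0)) abort("vertex weights must be strictly positive")
  selected <- character(0)
  while (igraph::vcount(g) > 0) {
    comp <- igraph::components(g)
    deg <- igraph::degree(g)
    w <- igraph::vertex_attr(g, "weight")
    nm <- igraph::vertex_attr(g, "name")
    f <- w / (deg + 1)
    drop <- integer(0)
    for (cc in seq_len(comp$no)) {
      idx <- which(comp$membership == cc)
      ord <- idx[order(-f[idx], -w[idx], nm[idx])]
      best <- ord[1]
      selected <- c(selected, nm[best])
      drop <- c(drop, best, as.integer(igraph::neighbors(g, best)))
    }
    g <- igraph::delete_vertices(g, unique(drop))
  }
  sort(selected)
}

#' Select the maximum-weighted independent cluster set
#'
#' Convenience wrapper: builds the overlap graph and runs the greedy
#' selection, returning the selected rows of the scored cluster table.
#'
#' @inheritParams build_overlap_graph
#' @return The subset of `scored` selected as the maximum-weighted
#'   independent set, with pairwise-disjoint locus sets.
#' @export
get_mwis <- function(scored) {
  g <- build_overlap_graph(scored)
  ids <- wmin_select(g)
  scored[scored$cluster_id %in% ids, , drop = FALSE]
}

#' Edge list of an overlap graph
#'
#' @param g An overlap graph.
#' @return Tibble with columns `from`, `to`, `w_from`, `w_to`.
#' @export
overlap_edges <- function(g) {
  e <- igraph::as_edgelist(g)
  w <- igraph::vertex_attr(g, "weight")
  nm <- igraph::vertex_attr(g, "name")
  tibble(from = e[, 1], to = e[, 2],
         w_from = w[match(e[, 1], nm)], w_to = w[match(e[, 2], nm)])
}
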