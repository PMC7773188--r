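#' One-shot MVS construction and analysis pipeline
#'
#' Chains the whole method on a filtered matrix set: multiple
#' density-based clustering over the (epsilon, minPts) grid, negative
#' binomial/size scoring, greedy maximum-weighted independent-set
#' selection, the occupancy/coverage MVS filters, and per-MVS
#' population-genomic statistics.
#'
#' @param matrices An `mvs_matrices` object from [filter_loci()] (or
#'   [read_mvs_matrices()]).
#' @inheritParams run_mdbscan
#' @inheritParams select_mvs
#' @inheritParams mvs_popgen
#' @return An object of class `mvs_set`: list with `matrices`, `clusters`
#'   (scored candidate tibble), `graph` (overlap graph), `mwis` (selected
#'   rows), `selection` (`mvs_set_selection`), `popgen` (`mvs_popgen`)
#'   and `params`.
#' @export
mvs_pipeline <- function(matrices, eps_values, p_values,
                         min_cluster_size = 1000L,
                         transform = c("none", "log1p"),
                         k_min = 4L, c_m = 8, m_min2 = 100L, n_sd = 2,
                         alpha = 0.05,
                         var_type = c("population", "sample"),
                         aggregate = c("mean", "ratio")) {
  transform <- match.arg(transform)
  var_type <- match.arg(var_type)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(matrices, "mvs_matrices"))
  params <- list(eps_values = eps_values, p_values = p_values,
                 min_cluster_size = min_cluster_size, transform = transform,
                 k_min = k_min, c_m = c_m, m_min2 = m_min2, n_sd = n_sd,
                 alpha = alpha, var_type = var_type, aggregate = aggregate)
  empty <- function(clusters, graph, mwis, selection) {
    structure(list(matrices = matrices, clusters = clusters, graph = graph,
                   mwis = mwis, selection = selection,
                   popgen = structure(list(), class = "mvs_popgen",
                                      alpha = alpha),
                   params = params),
              class = "mvs_set")
  }
  mvcs <- run_mdbscan(matrices, eps_values, p_values,
                      min_cluster_size = min_cluster_size,
                      transform = transform)
  if (nrow(mvcs) == 0) {
    return(empty(mvcs, igraph::make_empty_graph(0, directed = FALSE), mvcs,
                 select_mvs_empty()))
  }
  scored <- score_clusters(mvcs, matrices)
  graph <- build_overlap_graph(scored)
  mwis <- scored[scored$cluster_id %in% wmin_select(graph), , drop = FALSE]
  selection <- select_mvs(mwis, matrices, k_min = k_min, c_m = c_m,
                          m_min2 = m_min2, n_sd = n_sd)
  popgen <- mvs_popgen(selection, matrices, alpha = alpha,
                       var_type = var_type, aggregate = aggregate)
  structure(list(matrices = matrices, clusters = scored, graph = graph,
                 mwis = mwis, selection = selection, popgen = popgen,
                 params = params),
            class = "mvs_set")
}

select_mvs_empty <- function() {
  structure(list(
    mvs = tibble(mvs_id = character(), cluster_id = character(),
                 epsilon = numeric(), min_points = integer(),
                 n_loci_before = integer(), n_loci_after = integer(),
                 samples_passing = integer(), w = numeric(), loci = list()),
    dropped = tibble(cluster_id = character(), reason = character()),
    params = list()), class = "mvs_set_selection")
}

#' @export
print.mvs_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<mvs_set> %d candidate cluster(s) -> %d independent -> %d MVS\n"),
    nrow(x$clusters), nrow(x$mwis), nrow(x$selection$mvs)))
  if (nrow(x$selection$mvs) > 0) print(glance(x))
  invisible(x)
}

#' Tidy summaries of a fitted MVS set
#'
#' `tidy()` returns one row per metavariant species (provenance, sizes,
#' weight, mean F_ST, outlier count); with `what = "loci"` one row per
#' retained locus with its population-genomic statistics; with
#' `what = "clusters"` the scored candidate table. `glance()` returns a
#' one-row pipeline summary.
#'
#' @param x An `mvs_set` from [mvs_pipeline()].
#' @param what One of `"mvs"`, `"loci"`, `"clusters"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mvs_set
#' @export
tidy.mvs_set <- function(x, what = c("mvs", "loci", "clusters"), ...) {
  what <- match.arg(what)
  if (what == "clusters") return(dplyr::select(x$clusters, -"loci"))
  if (what == "loci") return(tidy(x$popgen))
  base <- dplyr::select(x$selection$mvs, -"loci")
  if (length(x$popgen) == 0) return(base)
  left_join(base, glance(x$popgen), by = "mvs_id")
}

#' @rdname tidy.mvs_set
#' @method glance mvs_set
#' @export
glance.mvs_set <- function(x, ...) {
  tibble(n_candidates = nrow(x$clusters),
         n_independent = nrow(x$mwis),
         n_mvs = nrow(x$selection$mvs),
         n_loci_assigned = sum(x$selection$mvs$n_loci_after),
         mean_fst = mean(purrr::map_dbl(unclass(x$popgen), "mean_fst")),
         n_outliers = sum(purrr::map_int(
           unclass(x$popgen), ~ sum(.x$per_locus$outlier))))
}
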