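#' Density-based clustering of the coverage matrix
#'
#' Runs DBSCAN on the rows of the depth-of-coverage matrix under Euclidean
#' distance. A locus is a core point iff its closed
#' epsilon-neighbourhood (itself included) holds at least `min_points`
#' loci; clusters are the maximal density-connected sets grown from core
#' points; the remaining loci are noise. Expansion proceeds in matrix row
#' order, so border loci reachable from several clusters deterministically
#' join the first cluster that claims them.
#'
#' @param coverage An `mvs_matrices` object, a wide coverage tibble (first
#'   column `locus_id`) or a numeric matrix with locus row names.
#' @param epsilon Neighbourhood radius (Euclidean), > 0.
#' @param min_points Minimum neighbourhood size for a core point, >= 1.
#' @param transform `"none"` (default) clusters raw depths; `"log1p"`
#'   clusters `log(1 + depth)`, which stabilises the strongly
#'   mean-dependent variance of overdispersed counts.
#' @return A tibble with one row per locus: `locus_id`, `cluster`
#'   (integer; 0 = noise, clusters numbered from 1 in order of discovery).
#' @examples
#' x <- matrix(c(0, 0.5, 1, 10, 10.5, 11), ncol = 1,
#'             dimnames = list(paste0("l", 1:6), "s1"))
#' dbscan_clusters(x, epsilon = 1, min_points = 3)
#' @export
dbscan_clusters <- function(coverage, epsilon, min_points,
                            transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  mat <- coerce_depth_matrix(coverage)
  if (nrow(mat) == 0) abort("empty coverage matrix")
  stopifnot(epsilon > 0, min_points >= 1)
  if (transform == "log1p") mat <- log1p(mat)
  nb <- eps_neighbours_cpp(mat, epsilon)
  labels <- dbscan_from_neighbours_cpp(nb, as.integer(min_points))
  tibble(locus_id = rownames(mat), cluster = as.integer(labels))
}

coerce_depth_matrix <- function(coverage) {
  if (inherits(coverage, "mvs_matrices")) coverage <- coverage$coverage
  if (is.data.frame(coverage)) coverage <- tibble_to_matrix(coverage)
  storage.mode(coverage) <- "double"
  if (is.null(rownames(coverage))) {
    rownames(coverage) <- paste0("locus", seq_len(nrow(coverage)))
  }
  coverage
}

#' Multiple density-based clustering over a parameter grid
#'
#' Runs [dbscan_clusters()] over the Cartesian grid of `eps_values` by
#' `p_values` and pools all clusters larger than `min_cluster_size` into
#' one candidate set. Clusters from the same run are disjoint by
#' construction; clusters from different runs may overlap — selecting a
#' non-overlapping subset is the job of [wmin_select()].
#'
#' There is no canonical default grid: the useful epsilon scale depends
#' entirely on the magnitude and transform of the depth matrix, so both
#' grids must be supplied.
#'
#' @inheritParams dbscan_clusters
#' @param eps_values Numeric vector of epsilon values.
#' @param p_values Integer vector of `min_points` values.
#' @param min_cluster_size Pooled clusters must contain strictly more than
#'   this many metavariants (default 1000).
#' @return A tibble of candidate clusters (the `MVC` set), one row per
#'   cluster: `cluster_id`, `epsilon`, `min_points`, `cluster_index`,
#'   `n_loci` and a list-column `loci` of locus id vectors.
#' @export
run_mdbscan <- function(coverage, eps_values, p_values,
                        min_cluster_size = 1000L,
                        transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  if (length(eps_values) == 0 || length(p_values) == 0) {
    abort("empty parameter grid")
  }
  mat <- coerce_depth_matrix(coverage)
  if (nrow(mat) == 0) abort("empty coverage matrix")
  tmat <- if (transform == "log1p") log1p(mat) else mat

  out <- list()
  for (eps in sort(eps_values)) {
    nb <- eps_neighbours_cpp(tmat, eps)
    for (p in sort(p_values)) {
      labels <- dbscan_from_neighbours_cpp(nb, as.integer(p))
      sizes <- tabulate(labels)
      for (k in which(sizes > min_cluster_size)) {
        out[[length(out) + 1L]] <- tibble(
          cluster_id = sprintf("e%s_p%s_c%d", format(eps), format(p), k),
          epsilon = eps, min_points = as.integer(p), cluster_index = k,
          n_loci = sizes[k],
          loci = list(rownames(mat)[labels == k]))
      }
    }
  }
  if (length(out) == 0) {
    warn("no cluster exceeded `min_cluster_size` anywhere on the grid")
    return(tibble(cluster_id = character(), epsilon = numeric(),
                  min_points = integer(), cluster_index = integer(),
                  n_loci = integer(), loci = list()))
  }
  bind_rows(out)
}

#' Long membership table of a candidate-cluster set
#'
#' @param mvcs A candidate-cluster tibble from [run_mdbscan()].
#' @return A tibble with columns `locus_id`, `epsilon`, `min_points`,
#'   `cluster_index` — the TSV interchange format for cluster memberships.
#' @export
cluster_membership <- function(mvcs) {
  tidyr::unnest(
    dplyr::select(mvcs, "epsilon", "min_points", "cluster_index",
                  locus_id = "loci"),
    "locus_id")[, c("locus_id", "epsilon", "min_points", "cluster_index")]
}
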