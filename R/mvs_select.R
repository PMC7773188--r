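#' Promote independent clusters to metavariant species
#'
#' Applies the occupancy and coverage criteria, in order, to each cluster
#' of the maximum-weighted independent set:
#'
#' 1. membership in the independent set is a precondition (the input);
#' 2. strictly more than `k_min` samples must have a median depth of the
#'    cluster's loci of at least `c_m` — allele frequencies are only
#'    trustworthy where the species is covered well enough;
#' 3. per sample, loci are kept only if their depth lies within
#'    `[max(c_m, median_j - n_sd * sd_j), median_j + n_sd * sd_j]` in
#'    every sample, where `median_j` and `sd_j` (sample standard
#'    deviation) are taken over the cluster's loci in sample `j` — this
#'    strips repeated regions and mis-clustered loci whose coverage does
#'    not match the species signature;
#' 4. strictly more than `m_min2` loci must survive the coverage filter.
#'
#' Clusters failing any criterion are dropped with a recorded reason.
#'
#' @param selected Scored cluster tibble restricted to the independent set
#'   (output of [get_mwis()]).
#' @param coverage Coverage source aligned with the clusters.
#' @param k_min Minimum number of well-covered samples (strictly
#'   exceeded), default 4.
#' @param c_m Median-depth threshold and lower coverage floor, default 8.
#' @param m_min2 Minimum number of retained loci (strictly exceeded),
#'   default 100.
#' @param n_sd Width of the coverage band in standard deviations,
#'   default 2.
#' @return An object of class `mvs_set_selection`: list with `mvs`
#'   (tibble: `mvs_id`, `cluster_id`, `epsilon`, `min_points`,
#'   `n_loci_before`, `n_loci_after`, `samples_passing`, `w`, list-column
#'   `loci` of retained locus ids) and `dropped` (tibble: `cluster_id`,
#'   `reason`).
#' @export
select_mvs <- function(selected, coverage, k_min = 4L, c_m = 8, m_min2 = 100L,
                       n_sd = 2) {
  stopifnot(k_min > 0, c_m > 0, m_min2 > 0, n_sd > 0)
  mat <- coerce_depth_matrix(coverage)
  if (k_min > ncol(mat)) abort("`k_min` exceeds the sample count")

  kept <- list()
  dropped <- list()
  ord <- order(-selected$w, selected$cluster_id)
  for (i in ord) {
    row <- selected[i, , drop = FALSE]
    sub <- mat[row$loci[[1]], , drop = FALSE]
    med <- apply(sub, 2, median)
    samples_passing <- sum(med >= c_m)
    if (!(samples_passing > k_min)) {
      dropped[[length(dropped) + 1L]] <- tibble(
        cluster_id = row$cluster_id,
        reason = sprintf("only %d sample(s) with median depth >= %g",
                         samples_passing, c_m))
      next
    }
    retained <- coverage_band_filter(sub, c_m = c_m, n_sd = n_sd)
    if (!(length(retained) > m_min2)) {
      dropped[[length(dropped) + 1L]] <- tibble(
        cluster_id = row$cluster_id,
        reason = sprintf("%d locus/loci within coverage bounds (need > %d)",
                         length(retained), m_min2))
      next
    }
    kept[[length(kept) + 1L]] <- tibble(
      cluster_id = row$cluster_id, epsilon = row$epsilon,
      min_points = row$min_points,
      n_loci_before = row$n_loci, n_loci_after = length(retained),
      samples_passing = samples_passing, w = row$w,
      loci = list(retained))
  }
  mvs <- if (length(kept) > 0) {
    out <- bind_rows(kept)
    dplyr::bind_cols(tibble(mvs_id = paste0("mvs", seq_len(nrow(out)))), out)
  } else {
    tibble(mvs_id = character(), cluster_id = character(),
           epsilon = numeric(), min_points = integer(),
           n_loci_before = integer(), n_loci_after = integer(),
           samples_passing = integer(), w = numeric(), loci = list())
  }
  dropped <- if (length(dropped) > 0) bind_rows(dropped) else
    tibble(cluster_id = character(), reason = character())
  if (nrow(dropped) > 0) {
    inform(paste0("dropped ", nrow(dropped), " cluster(s): ",
                  paste(dropped$cluster_id, dropped$reason, sep = ": ",
                        collapse = "; ")))
  }
  structure(list(mvs = mvs, dropped = dropped,
                 params = list(k_min = k_min, c_m = c_m, m_min2 = m_min2,
                               n_sd = n_sd)),
            class = "mvs_set_selection")
}

# loci whose depth lies within [max(c_m, med - n_sd*sd), med + n_sd*sd]
# in every sample, bounds computed per sample over the given loci
coverage_band_filter <- function(depths, c_m = 8, n_sd = 2) {
  med <- apply(depths, 2, median)
  sds <- apply(depths, 2, sd)
  lower <- pmax(c_m, med - n_sd * sds)
  upper <- med + n_sd * sds
  ok <- sweep(depths, 2, lower, ">=") & sweep(depths, 2, upper, "<=")
  rownames(depths)[rowSums(ok) == ncol(depths)]
}

#' Per-sample coverage bounds used by the MVS coverage filter
#'
#' Exposes the interval computed by criterion 3 of [select_mvs()] for one
#' cluster, mainly for inspection and testing.
#'
#' @param depths Numeric matrix (loci x samples) of the cluster's depths,
#'   or a vector for a single sample.
#' @inheritParams select_mvs
#' @return Tibble with one row per sample: `sample`, `median`, `sd`,
#'   `lower`, `upper`.
#' @export
coverage_bounds <- function(depths, c_m = 8, n_sd = 2) {
  if (is.null(dim(depths))) depths <- matrix(depths, ncol = 1,
                                             dimnames = list(NULL, "s1"))
  med <- unname(apply(depths, 2, median))
  sds <- unname(apply(depths, 2, sd))
  tibble(sample = colnames(depths), median = med, sd = sds,
         lower = pmax(c_m, med - n_sd * sds), upper = med + n_sd * sds)
}

#' @export
print.mvs_set_selection <- function(x, ...) {
  cat(sprintf("<mvs_set_selection> %d MVS retained, %d cluster(s) dropped\n",
              nrow(x$mvs), nrow(x$dropped)))
  if (nrow(x$mvs) > 0) print(dplyr::select(x$mvs, -"loci"))
  invisible(x)
}
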