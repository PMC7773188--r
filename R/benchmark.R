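#' Run the full method on the reference simulated community
#'
#' Generates the standard six-species, seven-sample community
#' ([six_species_community()]), filters loci with the usual simulated-data
#' parameters (cumulative depth in \[10, 500\], occurrence in every
#' retained sample), runs the whole pipeline on log-stabilised depths over
#' the default epsilon/minPts grid, and scores the recovered metavariant
#' species against the planted truth.
#'
#' Differentiation accuracy is measured exactly the way a reference-based
#' control would: for every recovered MVS, its between-sample pairwise
#' F_ST matrix is compared entrywise with the matrix obtained from the
#' loci truly belonging to the species the MVS was assigned to, with the
#' same coverage-band locus filter applied on the truth side. The summary
#' `delta_fst_max` is the maximum absolute difference over all sample
#' pairs and all recovered species.
#'
#' @param seed Integer seed for the community simulation.
#' @param samples Optional subset of samples (ids or positions) on which
#'   to run the analysis; default all seven.
#' @param n_loci Loci per species, default 2000.
#' @param eps_values,p_values The clustering grid. The default epsilon
#'   grid spans the useful density scales of the log-transformed
#'   community, scaled by `sqrt(m / 7)` because Euclidean distances
#'   between loci grow with the square root of the number of samples.
#' @param alpha LK outlier threshold, default 0.05.
#' @return List with `sim` (the dataset), `matrices` (filtered),
#'   `result` (the `mvs_set`), `evaluation` (per-MVS assignment and
#'   recall/precision/STN plus global purity/entropy), `delta_fst`
#'   (tibble: `mvs_id`, `species`, `delta_max`) and `delta_fst_max`.
#' @export
community_benchmark <- function(seed, samples = NULL, n_loci = 2000,
                                eps_values = NULL,
                                p_values = c(20, 40, 80),
                                alpha = 0.05) {
  sim <- simulate_mvs_dataset(six_species_community(n_loci = n_loci), seed)
  records <- as_metavar_records(sim)
  mats <- filter_loci(records, min_cum_depth = 10, max_cum_depth = 500,
                      min_samples = NULL)
  if (!is.null(samples)) mats <- select_samples(mats, samples)
  m <- length(sample_ids(mats))
  if (is.null(eps_values)) {
    eps_values <- c(0.5, 0.6, 0.7, 0.8) * sqrt(m / 7)
  }

  result <- mvs_pipeline(mats, eps_values = eps_values, p_values = p_values,
                         min_cluster_size = 1000L, transform = "log1p",
                         alpha = alpha)

  if (nrow(result$selection$mvs) == 0) {
    return(list(sim = sim, matrices = mats, result = result,
                evaluation = NULL,
                delta_fst = tibble(mvs_id = character(),
                                   species = character(),
                                   delta_max = numeric()),
                delta_fst_max = NA_real_))
  }
  evaluation <- evaluate_clustering(result$selection$mvs, sim$truth)

  depth <- tibble_to_matrix(mats$coverage)
  freq <- tibble_to_matrix(allele_frequencies(mats))
  p <- result$params
  deltas <- purrr::map2(
    result$selection$mvs$mvs_id, evaluation$per_cluster$species,
    function(id, species) {
      truth_loci <- intersect(
        sim$truth$locus_id[sim$truth$species == species], rownames(depth))
      truth_loci <- coverage_band_filter(
        depth[truth_loci, , drop = FALSE], c_m = p$c_m, n_sd = p$n_sd)
      ref <- pairwise_fst(freq[truth_loci, , drop = FALSE],
                          var_type = p$var_type, aggregate = p$aggregate)
      est <- result$popgen[[id]]$pairwise
      tibble(mvs_id = id, species = species,
             delta_max = max(abs(est - ref)))
    })
  delta_fst <- bind_rows(deltas)
  list(sim = sim, matrices = mats, result = result, evaluation = evaluation,
       delta_fst = delta_fst, delta_fst_max = max(delta_fst$delta_max))
}
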