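#' Assign clusters to ground-truth species
#'
#' Each cluster is labelled with the species contributing the highest
#' proportion of its members (plurality vote). Loci absent from the truth
#' table are excluded from the proportions (with a message); ties are
#' broken by lexicographically smallest species label and recorded.
#'
#' @param clusters A tibble with columns `cluster_id` (or `mvs_id`) and a
#'   list-column `loci`, or a named list of locus-id vectors.
#' @param truth Tibble with columns `locus_id` and `species`.
#' @return Tibble with columns `cluster_id`, `species`, `n_labelled`,
#'   `tie` (logical).
#' @export
assign_clusters <- function(clusters, truth) {
  cl <- normalise_clusters(clusters)
  lookup <- setNames(as.character(truth$species),
                     as.character(truth$locus_id))
  miss <- 0L
  rows <- purrr::imap(cl, function(ids, id) {
    if (length(ids) == 0) abort(paste0("empty cluster: ", id))
    lab <- lookup[as.character(ids)]
    miss <<- miss + sum(is.na(lab))
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) {
      return(tibble(cluster_id = id, species = NA_character_,
                    n_labelled = 0L, tie = FALSE))
    }
    counts <- sort(table(lab), decreasing = TRUE)
    top <- names(counts)[counts == max(counts)]
    tibble(cluster_id = id, species = sort(top)[1],
           n_labelled = length(lab), tie = length(top) > 1)
  })
  if (miss > 0) {
    inform(sprintf("%d locus/loci absent from the truth table excluded", miss))
  }
  out <- bind_rows(rows)
  if (any(out$tie)) {
    inform(paste0("plurality tie(s) broken lexicographically for: ",
                  paste(out$cluster_id[out$tie], collapse = ", ")))
  }
  out
}

normalise_clusters <- function(clusters) {
  if (is.data.frame(clusters)) {
    idcol <- intersect(c("cluster_id", "mvs_id"), names(clusters))[1]
    if (is.na(idcol) || !"loci" %in% names(clusters)) {
      abort("cluster tibble needs an id column and a `loci` list-column")
    }
    setNames(clusters$loci, clusters[[idcol]])
  } else {
    if (is.null(names(clusters))) {
      names(clusters) <- paste0("cluster", seq_along(clusters))
    }
    clusters
  }
}

#' Per-cluster recall, precision and signal-to-noise
#'
#' Against an assigned species, `TP` is the number of cluster members of
#' that species, `FP` the members of other species, `FN` the loci of the
#' species (anywhere in the truth table) outside the cluster. Then
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)` and
#' `STN = recall / (1 - precision)`, reported as `Inf` when precision is
#' exactly 1 — a cluster free of false positives has unbounded
#' signal-to-noise.
#'
#' @param cluster Character vector of locus ids (one cluster).
#' @param species The species label the cluster is assigned to.
#' @param truth Tibble with columns `locus_id` and `species`.
#' @return One-row tibble: `tp`, `fp`, `fn`, `recall`, `precision`, `stn`.
#' @export
cluster_metrics <- function(cluster, species, truth) {
  lookup <- setNames(as.character(truth$species),
                     as.character(truth$locus_id))
  lab <- lookup[as.character(cluster)]
  lab <- lab[!is.na(lab)]
  tp <- sum(lab == species)
  fp <- sum(lab != species)
  fn <- sum(lookup == species) - tp
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  stn <- if (tp == 0) 0 else if (precision == 1) Inf else
    recall / (1 - precision)
  tibble(tp = tp, fp = fp, fn = fn, recall = recall, precision = precision,
         stn = stn)
}

#' Purity and entropy of a whole clustering
#'
#' `purity` is the fraction of clustered loci matching their cluster's
#' plurality species: `(1/n) * sum_q max_j n_qj`, with `n` counting only
#' clustered loci. `entropy` is by default the plain sum over clusters of
#' within-cluster label entropies,
#' `- sum_q sum_j (n_qj / n_q) log2(n_qj / n_q)`; `weighted = TRUE`
#' instead weights each cluster's entropy by its size share `n_q / n`
#' (the conventional variant).
#'
#' @inheritParams assign_clusters
#' @param weighted Use the size-weighted entropy variant (default FALSE).
#' @return One-row tibble with `purity` and `entropy`.
#' @export
clustering_metrics <- function(clusters, truth, weighted = FALSE) {
  cl <- normalise_clusters(clusters)
  if (length(cl) == 0) abort("need at least one cluster")
  lookup <- setNames(as.character(truth$species),
                     as.character(truth$locus_id))
  tabs <- purrr::map(cl, function(ids) {
    lab <- lookup[as.character(ids)]
    table(lab[!is.na(lab)])
  })
  n <- sum(purrr::map_int(tabs, sum))
  purity <- sum(purrr::map_int(tabs, max)) / n
  ent <- purrr::map_dbl(tabs, function(tt) {
    pr <- tt / sum(tt)
    -sum(pr * log2(pr))
  })
  entropy <- if (weighted) {
    sum(purrr::map_int(tabs, sum) / n * ent)
  } else {
    sum(ent)
  }
  tibble(purity = purity, entropy = entropy)
}

#' Evaluate a clustering against truth labels
#'
#' Convenience wrapper joining [assign_clusters()], [cluster_metrics()]
#' per cluster and [clustering_metrics()].
#'
#' @inheritParams assign_clusters
#' @param weighted Passed to [clustering_metrics()].
#' @return List with `per_cluster` (tibble: assignment plus metrics) and
#'   `global` (one-row purity/entropy tibble).
#' @export
evaluate_clustering <- function(clusters, truth, weighted = FALSE) {
  cl <- normalise_clusters(clusters)
  assignment <- assign_clusters(cl, truth)
  metrics <- purrr::map2(cl[assignment$cluster_id], assignment$species,
                         cluster_metrics, truth = truth)
  list(per_cluster = dplyr::bind_cols(assignment, bind_rows(metrics)),
       global = clustering_metrics(cl, truth, weighted = weighted))
}
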