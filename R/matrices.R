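#' Locus filtering and matrix construction
#'
#' Builds the three aligned loci-by-samples matrices used by every
#' downstream stage — depth of coverage, per-allele read counts and allele
#' frequencies — from a long table of per-sample metavariant read counts,
#' applying the standard locus filters on the way.
#'
#' A locus is retained iff (i) its cumulative depth across samples lies in
#' `[min_cum_depth, max_cum_depth]` and (ii) it occurs (depth > 0) in at
#' least `min_samples` samples. The defaults reproduce the usual
#' simulated-data invocation `-a 10 -b 500 -c m` where `m` is the sample
#' count.
#'
#' @param records Long tibble with columns `locus_id`, `sample`, `count_a`
#'   and `count_b` (read counts supporting the two alleles), as returned by
#'   [read_metavar_vcf()] or [as_metavar_records()].
#' @param min_cum_depth Minimum cumulative depth of a locus across samples
#'   (the `-a` filter).
#' @param max_cum_depth Maximum cumulative depth across samples (`-b`).
#' @param min_samples Minimum number of samples in which the locus must
#'   occur, i.e. have depth > 0 (`-c`). `NULL` (default) requires presence
#'   in every sample.
#' @return An object of class `mvs_matrices`: a list with wide tibbles
#'   `coverage`, `counts_a`, `counts_b` and `freq` (first column
#'   `locus_id`, one column per sample; `freq` is `count_a / depth`, `NA`
#'   where depth is zero), plus the filter parameters used.
#' @examples
#' sim <- simulate_mvs_dataset(
#'   list(species_spec("spA", 50, c(20, 30, 40), strain_fractions = c(.2, .5, .8))),
#'   seed = 1)
#' filter_loci(as_metavar_records(sim), min_cum_depth = 10, max_cum_depth = 500)
#' @export
filter_loci <- function(records, min_cum_depth = 10L, max_cum_depth = 500L,
                        min_samples = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("locus_id", "sample", "count_a", "count_b")
  if (!all(needed %in% names(records))) {
    abort(paste0("`records` must have columns ",
                 paste(needed, collapse = ", ")))
  }
  samples <- if (is.factor(records$sample)) {
    levels(records$sample)
  } else {
    unique(as.character(records$sample))
  }
  m <- length(samples)
  if (is.null(min_samples)) min_samples <- m
  if (min_cum_depth < 0 || max_cum_depth < min_cum_depth) {
    abort("need 0 <= min_cum_depth <= max_cum_depth")
  }
  if (min_samples < 1 || min_samples > m) {
    abort("`min_samples` must be in [1, number of samples]")
  }
  if (any(records$count_a < 0, na.rm = TRUE) ||
      any(records$count_b < 0, na.rm = TRUE)) {
    abort("negative allele counts")
  }

  loci <- unique(as.character(records$locus_id))
  ia <- long_to_matrix(records, "count_a", loci, samples)
  ib <- long_to_matrix(records, "count_b", loci, samples)
  depth <- ia + ib

  keep <- rowSums(depth) >= min_cum_depth &
    rowSums(depth) <= max_cum_depth &
    rowSums(depth > 0) >= min_samples
  if (!any(keep)) {
    warn("no locus passes the filters; returning empty matrices")
  }
  depth <- depth[keep, , drop = FALSE]
  ia <- ia[keep, , drop = FALSE]
  ib <- ib[keep, , drop = FALSE]
  fr <- ifelse(depth > 0, ia / ifelse(depth > 0, depth, 1), NA_real_)

  new_mvs_matrices(
    coverage = depth, counts_a = ia, counts_b = ib, freq = fr,
    params = list(min_cum_depth = min_cum_depth,
                  max_cum_depth = max_cum_depth,
                  min_samples = min_samples),
    n_input = length(loci))
}

long_to_matrix <- function(records, col, loci, samples) {
  i <- match(as.character(records$locus_id), loci)
  j <- match(as.character(records$sample), samples)
  mat <- matrix(0, nrow = length(loci), ncol = length(samples),
                dimnames = list(loci, samples))
  v <- records[[col]]
  v[is.na(v)] <- 0
  mat[cbind(i, j)] <- v
  mat
}

new_mvs_matrices <- function(coverage, counts_a, counts_b, freq, params,
                             n_input = nrow(coverage)) {
  structure(
    list(coverage = matrix_to_tibble(coverage),
         counts_a = matrix_to_tibble(counts_a),
         counts_b = matrix_to_tibble(counts_b),
         freq = matrix_to_tibble(freq),
         params = params,
         n_input = n_input),
    class = "mvs_matrices")
}

#' @export
print.mvs_matrices <- function(x, ...) {
  cat(sprintf("<mvs_matrices> %d loci x %d samples (from %d input loci)\n",
              nrow(x$coverage), ncol(x$coverage) - 1L, x$n_input))
  cat(sprintf("  filters: cumulative depth in [%s, %s], occurrence in >= %s samples\n",
              x$params$min_cum_depth, x$params$max_cum_depth,
              x$params$min_samples))
  invisible(x)
}

#' Convert between wide locus tibbles and matrices
#'
#' Wide locus tibbles carry `locus_id` as their first column and one
#' numeric column per sample; these helpers move between that
#' representation and a plain matrix with locus ids as row names.
#'
#' @param tbl A wide tibble with a `locus_id` column.
#' @param mat A numeric matrix with locus ids as row names and sample ids
#'   as column names.
#' @return `tibble_to_matrix()` a matrix; `matrix_to_tibble()` a tibble.
#' @export
tibble_to_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "locus_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "locus_id")])
  rownames(m) <- as.character(tbl$locus_id)
  m
}

#' @rdname tibble_to_matrix
#' @export
matrix_to_tibble <- function(mat) {
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  out <- as_tibble(mat, .name_repair = "minimal")
  dplyr::bind_cols(tibble(locus_id = ids), out)
}

#' Sample identifiers of a matrix set
#' @param x An `mvs_matrices` object.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "mvs_matrices"))
  setdiff(names(x$coverage), "locus_id")
}

#' Restrict a matrix set to a subset of samples
#'
#' Drops the other sample columns from all four matrices and re-applies
#' the occurrence filter so that loci absent from the retained samples do
#' not linger. Used e.g. to study the effect of sample count on cluster
#' recovery.
#'
#' @param x An `mvs_matrices` object.
#' @param samples Character vector of sample ids (or integer positions).
#' @param refilter Re-apply the cumulative-depth and occurrence filters on
#'   the retained columns (default `TRUE`; occurrence is required in all
#'   retained samples when the original call did).
#' @return A new `mvs_matrices` object.
#' @export
select_samples <- function(x, samples, refilter = TRUE) {
  stopifnot(inherits(x, "mvs_matrices"))
  ids <- sample_ids(x)
  if (is.numeric(samples)) samples <- ids[samples]
  stopifnot(all(samples %in% ids))
  all_kept <- x$params$min_samples >= length(ids)
  rec <- as_metavar_records(x)
  rec <- rec[rec$sample %in% samples, , drop = FALSE]
  rec$sample <- factor(rec$sample, levels = samples)
  if (refilter) {
    filter_loci(rec,
                min_cum_depth = x$params$min_cum_depth,
                max_cum_depth = x$params$max_cum_depth,
                min_samples = if (all_kept) length(samples) else
                  min(x$params$min_samples, length(samples)))
  } else {
    filter_loci(rec, min_cum_depth = 0L,
                max_cum_depth = .Machine$integer.max, min_samples = 1L)
  }
}

#' Long record table from matrices or simulations
#'
#' @param x An `mvs_matrices` object or an `mvs_sim` dataset.
#' @return A long tibble with columns `locus_id`, `sample`, `count_a`,
#'   `count_b`, one row per locus/sample pair — the input format of
#'   [filter_loci()].
#' @export
as_metavar_records <- function(x) UseMethod("as_metavar_records")

#' @export
as_metavar_records.mvs_matrices <- function(x) {
  records_from_wide(x$counts_a, x$counts_b)
}

records_from_wide <- function(wide_a, wide_b) {
  samples <- setdiff(names(wide_a), "locus_id")
  la <- tidyr::pivot_longer(wide_a, dplyr::all_of(samples),
                            names_to = "sample", values_to = "count_a")
  lb <- tidyr::pivot_longer(wide_b, dplyr::all_of(samples),
                            names_to = "sample", values_to = "count_b")
  out <- dplyr::bind_cols(la, lb["count_b"])
  out$sample <- factor(out$sample, levels = samples)
  out
}

#' Write and read the TSV interchange matrices
#'
#' The on-disk interchange format is three TSV files per matrix set:
#' `<prefix>coverage.tsv` (integer depths), `<prefix>allele_counts.tsv`
#' (`"ca,cb"` pairs) and `<prefix>frequencies.tsv` (`NA` when depth is
#' zero). First column `locus_id`, header row of sample ids.
#'
#' @param x An `mvs_matrices` object.
#' @param dir Directory to write into (created if needed).
#' @param prefix Filename prefix, default `""`.
#' @return `write_mvs_matrices()` the directory, invisibly;
#'   `read_mvs_matrices()` an `mvs_matrices` object.
#' @export
write_mvs_matrices <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "mvs_matrices"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(x$coverage, file.path(dir, paste0(prefix, "coverage.tsv")))
  a <- tibble_to_matrix(x$counts_a)
  b <- tibble_to_matrix(x$counts_b)
  pairs <- matrix(paste0(a, ",", b), nrow = nrow(a), dimnames = dimnames(a))
  readr::write_tsv(matrix_to_tibble(pairs),
                   file.path(dir, paste0(prefix, "allele_counts.tsv")))
  readr::write_tsv(x$freq, file.path(dir, paste0(prefix, "frequencies.tsv")),
                   na = "NA")
  invisible(dir)
}

#' @rdname write_mvs_matrices
#' @export
read_mvs_matrices <- function(dir, prefix = "") {
  cov <- readr::read_tsv(file.path(dir, paste0(prefix, "coverage.tsv")),
                         show_col_types = FALSE)
  pairs <- readr::read_tsv(file.path(dir, paste0(prefix, "allele_counts.tsv")),
                           col_types = readr::cols(.default = "c"))
  pm <- tibble_to_matrix_chr(pairs)
  a <- apply(pm, 2, function(col) as.numeric(sub(",.*", "", col)))
  b <- apply(pm, 2, function(col) as.numeric(sub(".*,", "", col)))
  dimnames(a) <- dimnames(b) <- dimnames(pm)
  depth <- a + b
  fr <- ifelse(depth > 0, a / ifelse(depth > 0, depth, 1), NA_real_)
  new_mvs_matrices(
    coverage = tibble_to_matrix(cov), counts_a = a, counts_b = b, freq = fr,
    params = list(min_cum_depth = NA, max_cum_depth = NA, min_samples = NA))
}

tibble_to_matrix_chr <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "locus_id")])
  rownames(m) <- as.character(tbl$locus_id)
  m
}
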