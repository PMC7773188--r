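#' Allele frequencies from allele counts
#'
#' The frequency of allele `a` at a locus in a sample is
#' `p = c_a / (c_a + c_b)`; it is undefined (`NA`) where the locus has
#' zero depth. Which of the two alleles is tracked is inert downstream:
#' every statistic here is symmetric under `p -> 1 - p`.
#'
#' @param x An `mvs_matrices` object, or a list with wide tibbles
#'   `counts_a` and `counts_b`.
#' @return A wide frequency tibble (first column `locus_id`).
#' @export
allele_frequencies <- function(x) {
  a <- tibble_to_matrix(x$counts_a)
  b <- tibble_to_matrix(x$counts_b)
  depth <- a + b
  matrix_to_tibble(ifelse(depth > 0, a / ifelse(depth > 0, depth, 1),
                          NA_real_))
}

#' Per-locus global F_ST
#'
#' For each locus, `F_ST = Var(p) / (p_bar * (1 - p_bar))` across the
#' samples where the frequency is defined, with `p_bar` their mean and
#' `Var` by default the population variance (divisor `m`), which keeps
#' `F_ST` in \[0, 1\] and matches the Lewontin-Krakauer formulation.
#' Monomorphic loci (`p_bar` of 0 or 1) get `F_ST = 0` and are excluded
#' from the mean `F_ST` across loci, as are loci with fewer than two
#' defined samples (excluded entirely, with a message).
#'
#' @param freq Wide frequency tibble (or matrix) as produced by
#'   [allele_frequencies()].
#' @param var_type `"population"` (divisor m, default) or `"sample"`
#'   (divisor m - 1).
#' @return List with `per_locus` (tibble: `locus_id`, `n_samples`,
#'   `p_bar`, `fst`) and `mean_fst`.
#' @examples
#' f <- matrix(c(0.2, 0.4, 0.6), nrow = 1,
#'             dimnames = list("l1", c("s1", "s2", "s3")))
#' global_fst(f)$per_locus$fst  # 0.1111...
#' @export
global_fst <- function(freq, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  mat <- if (is.data.frame(freq)) tibble_to_matrix(freq) else freq
  n_def <- rowSums(!is.na(mat))
  excluded <- rownames(mat)[n_def < 2]
  if (length(excluded) > 0) {
    inform(sprintf(
      "%d locus/loci with fewer than 2 defined frequencies excluded",
      length(excluded)))
    mat <- mat[n_def >= 2, , drop = FALSE]
    n_def <- n_def[n_def >= 2]
  }
  p_bar <- rowMeans(mat, na.rm = TRUE)
  dev2 <- rowSums((mat - p_bar)^2, na.rm = TRUE)
  v <- dev2 / if (var_type == "population") n_def else (n_def - 1)
  denom <- p_bar * (1 - p_bar)
  mono <- denom == 0
  fst <- ifelse(mono, 0, v / ifelse(mono, 1, denom))
  per_locus <- tibble(locus_id = rownames(mat), n_samples = unname(n_def),
                      p_bar = unname(p_bar), fst = unname(fst))
  mean_fst <- if (all(mono)) NA_real_ else mean(fst[!mono])
  list(per_locus = per_locus, mean_fst = mean_fst)
}

#' Lewontin-Krakauer statistic and chi-square p-values
#'
#' `LK = (m - 1) * F_ST / mean F_ST`, which under neutral evolution of
#' most polymorphic loci is approximately chi-square distributed with
#' `m - 1` degrees of freedom (`m` = number of populations/samples). The
#' p-value is the upper-tail probability at the observed `LK`; loci with
#' unexpectedly large `LK` are candidates for natural selection.
#'
#' @param fst Numeric vector of per-locus `F_ST` values.
#' @param mean_fst Mean `F_ST` across loci (must be > 0).
#' @param m Number of samples.
#' @return Tibble with columns `lk` and `p_value`.
#' @export
lk_statistic <- function(fst, mean_fst, m) {
  if (!is.finite(mean_fst) || mean_fst <= 0) {
    abort("mean F_ST must be > 0 (all loci monomorphic?)")
  }
  stopifnot(m >= 2)
  lk <- (m - 1) * fst / mean_fst
  tibble(lk = lk, p_value = pchisq(lk, df = m - 1, lower.tail = FALSE))
}

#' Loci flagged as selection outliers
#'
#' @param per_locus Tibble with columns `locus_id` and `p_value` (e.g.
#'   from [mvs_popgen()] results or [lk_statistic()] joined to loci).
#' @param alpha Significance threshold; loci with `p_value <= alpha` are
#'   reported. 0.05 is the usual screening value, 0.001 a stricter one.
#' @return Character vector of outlier locus ids.
#' @export
selection_outliers <- function(per_locus, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  per_locus$locus_id[per_locus$p_value <= alpha]
}

#' Between-sample pairwise F_ST matrix
#'
#' For every pair of samples, the per-locus `F_ST` estimator restricted to
#' that pair is averaged over the loci with defined frequencies in both
#' samples. Loci monomorphic within the pair carry no differentiation
#' information and are excluded from the average, mirroring the treatment
#' of monomorphic loci in the global mean `F_ST`. `aggregate = "ratio"`
#' instead divides the summed variances by the summed heterozygosities
#' (a ratio-of-averages estimator).
#'
#' @inheritParams global_fst
#' @param aggregate `"mean"` (default) or `"ratio"`.
#' @return A symmetric `m x m` matrix with zero diagonal and sample ids as
#'   dimnames; entries are `NA` (with a message) for pairs sharing no
#'   informative locus.
#' @export
pairwise_fst <- function(freq, var_type = c("population", "sample"),
                         aggregate = c("mean", "ratio")) {
  var_type <- match.arg(var_type)
  aggregate <- match.arg(aggregate)
  mat <- if (is.data.frame(freq)) tibble_to_matrix(freq) else freq
  m <- ncol(mat)
  if (m < 2) abort("need at least 2 samples")
  divisor <- if (var_type == "population") 2 else 1
  out <- matrix(0, m, m, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      p1 <- mat[, i]
      p2 <- mat[, j]
      def <- !is.na(p1) & !is.na(p2)
      pb <- (p1 + p2) / 2
      het <- pb * (1 - pb)
      info <- def & het > 0
      if (!any(info)) {
        inform(sprintf("samples %s and %s share no informative locus",
                       colnames(mat)[i], colnames(mat)[j]))
        out[i, j] <- out[j, i] <- NA_real_
        next
      }
      v <- ((p1 - pb)^2 + (p2 - pb)^2) / divisor
      out[i, j] <- out[j, i] <- if (aggregate == "mean") {
        mean(v[info] / het[info])
      } else {
        sum(v[info]) / sum(het[info])
      }
    }
  }
  out
}

#' Population-genomic analysis of selected MVSs
#'
#' Runs the full statistics battery for every metavariant species: allele
#' frequencies over its retained loci, per-locus global `F_ST`, the
#' Lewontin-Krakauer statistic with chi-square upper-tail p-values and
#' outlier flags at `alpha`, and the between-sample pairwise `F_ST`
#' matrix.
#'
#' @param selection An `mvs_set_selection` from [select_mvs()].
#' @param matrices The `mvs_matrices` object holding the allele counts.
#' @param alpha Outlier significance threshold, default 0.05.
#' @inheritParams pairwise_fst
#' @return An object of class `mvs_popgen`: named list (one element per
#'   MVS) of lists with `per_locus` (tibble: `locus_id`, `p_bar`, `fst`,
#'   `lk`, `p_value`, `outlier`), `mean_fst` and `pairwise` (matrix);
#'   plus attribute `alpha`.
#' @export
mvs_popgen <- function(selection, matrices, alpha = 0.05,
                       var_type = c("population", "sample"),
                       aggregate = c("mean", "ratio")) {
  var_type <- match.arg(var_type)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(selection, "mvs_set_selection"),
            inherits(matrices, "mvs_matrices"))
  freq <- tibble_to_matrix(allele_frequencies(matrices))
  m <- ncol(freq)
  res <- purrr::map(seq_len(nrow(selection$mvs)), function(i) {
    ids <- selection$mvs$loci[[i]]
    f <- freq[ids, , drop = FALSE]
    gf <- global_fst(f, var_type = var_type)
    lk <- lk_statistic(gf$per_locus$fst, gf$mean_fst, m)
    per_locus <- dplyr::bind_cols(gf$per_locus, lk)
    per_locus$outlier <- per_locus$p_value <= alpha
    list(per_locus = per_locus, mean_fst = gf$mean_fst,
         pairwise = pairwise_fst(f, var_type = var_type,
                                 aggregate = aggregate))
  })
  names(res) <- selection$mvs$mvs_id
  structure(res, class = "mvs_popgen", alpha = alpha)
}

#' @export
print.mvs_popgen <- function(x, ...) {
  cat(sprintf("<mvs_popgen> %d MVS, alpha = %g\n", length(x),
              attr(x, "alpha")))
  for (id in names(x)) {
    cat(sprintf("  %s: %d loci, mean F_ST %.4f, %d outlier(s)\n", id,
                nrow(x[[id]]$per_locus), x[[id]]$mean_fst,
                sum(x[[id]]$per_locus$outlier)))
  }
  invisible(x)
}

#' @method tidy mvs_popgen
#' @export
tidy.mvs_popgen <- function(x, ...) {
  purrr::list_rbind(purrr::imap(unclass(x), function(r, id) {
    dplyr::bind_cols(tibble(mvs_id = id), r$per_locus)
  }))
}

#' @method glance mvs_popgen
#' @export
glance.mvs_popgen <- function(x, ...) {
  purrr::list_rbind(purrr::imap(unclass(x), function(r, id) {
    tibble(mvs_id = id, n_loci = nrow(r$per_locus), mean_fst = r$mean_fst,
           n_outliers = sum(r$per_locus$outlier),
           max_pairwise_fst = max(r$pairwise, na.rm = TRUE))
  }))
}
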