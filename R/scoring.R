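#' Floor used for strictly positive cluster weights
#'
#' Min-max normalisation necessarily sends at least one cluster to 0 on
#' each score axis, but the independent-set selection requires strictly
#' positive weights, so clusters whose normalised score product is zero
#' receive this small positive weight instead.
#' @export
MVS_WEIGHT_FLOOR <- 1e-6

#' Maximum-likelihood negative-binomial fit of depth counts
#'
#' Fits a negative binomial distribution, parameterised by mean `mu` and
#' dispersion (size) `r`, to a vector of non-negative integer depths by
#' numerical maximum likelihood with method-of-moments initialisation (via
#' \pkg{fitdistrplus}). Sequencing depth of coverage is overdispersed
#' relative to Poisson, which is why the NB is the reference model here.
#'
#' Underdispersed input (variance <= mean) makes the MLE of `r` diverge;
#' such fits degenerate toward Poisson and are returned with `r` capped at
#' a large value and a note, rather than failing.
#'
#' @param counts Non-negative integer vector, length >= 2, not all zero.
#' @return An object of class `nb_fit`: list with `size` (r), `mu`,
#'   `log_likelihood`, `n` and `method` (`"mle"` or `"moment_cap"`).
#' @examples
#' fit_negative_binomial(rnbinom(500, mu = 30, size = 5))
#' @export
fit_negative_binomial <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) abort("need at least 2 observations")
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("counts must be non-negative and non-missing")
  }
  if (all(counts == 0)) abort("all-zero counts: no NB fit exists")

  mu0 <- mean(counts)
  v0 <- var(counts)
  cap <- 1e8
  if (v0 <= mu0) {
    # variance <= mean: Poisson-degenerate branch
    inform(sprintf(
      "underdispersed counts (var %.3g <= mean %.3g): capping dispersion",
      v0, mu0))
    ll <- sum(dnbinom(counts, size = cap, mu = mu0, log = TRUE))
    return(new_nb_fit(cap, mu0, ll, length(counts), "moment_cap"))
  }
  fit <- tryCatch(
    suppressWarnings(fitdistrplus::fitdist(
      counts, "nbinom",
      start = list(size = mu0^2 / (v0 - mu0), mu = mu0))),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$estimate)) || !is.finite(fit$loglik)) {
    inform("NB MLE failed to converge; falling back to capped dispersion")
    ll <- sum(dnbinom(counts, size = cap, mu = mu0, log = TRUE))
    return(new_nb_fit(cap, mu0, ll, length(counts), "moment_cap"))
  }
  new_nb_fit(unname(fit$estimate["size"]), unname(fit$estimate["mu"]),
             fit$loglik, length(counts), "mle")
}

new_nb_fit <- function(size, mu, ll, n, method) {
  structure(list(size = size, mu = mu, log_likelihood = ll, n = n,
                 method = method),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit> mu = %.4g, size = %.4g, logLik = %.4g (n = %d, %s)\n",
              x$mu, x$size, x$log_likelihood, x$n, x$method))
  invisible(x)
}

#' @method tidy nb_fit
#' @export
tidy.nb_fit <- function(x, ...) {
  tibble(term = c("mu", "size"), estimate = c(x$mu, x$size))
}

#' @method glance nb_fit
#' @export
glance.nb_fit <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood, n = x$n, method = x$method)
}

#' Score candidate clusters by NB fit and size
#'
#' For every candidate cluster, each sample's depths over the cluster's
#' loci are fitted with a negative binomial; `d` is the mean across
#' samples of the total per-sample log-likelihood at the optimum. `d` and
#' the cluster size `s` are then min-max normalised across the whole
#' candidate set to `d_bar` and `s_bar` in \[0, 1\], and the cluster
#' weight is their geometric mean `w = sqrt(d_bar * s_bar)`, floored at
#' [MVS_WEIGHT_FLOOR] so that all weights are strictly positive.
#'
#' A single-cluster input has no competitors: both normalised scores are 1
#' by convention. Likewise when all clusters tie on an axis, that axis is
#' set to 1 for everyone.
#'
#' @param mvcs Candidate-cluster tibble from [run_mdbscan()].
#' @param coverage The same coverage source the clusters were built from
#'   (`mvs_matrices`, wide tibble or matrix). Raw depths are always used
#'   for scoring, whatever transform the clustering used.
#' @return The input tibble with columns `d`, `d_bar`, `s_bar`, `w`
#'   appended, one row per cluster (order preserved).
#' @export
score_clusters <- function(mvcs, coverage) {
  if (nrow(mvcs) == 0) abort("no clusters to score")
  mat <- coerce_depth_matrix(coverage)
  missing <- setdiff(unique(unlist(mvcs$loci)), rownames(mat))
  if (length(missing) > 0) {
    abort(paste0("cluster loci absent from coverage matrix, e.g. ",
                 missing[1]))
  }
  d <- purrr::map_dbl(mvcs$loci, function(ids) {
    sub <- mat[ids, , drop = FALSE]
    mean(apply(sub, 2, sample_nb_loglik))
  })
  s <- purrr::map_int(mvcs$loci, length)
  mvcs$d <- d
  mvcs$n_loci <- s
  dplyr::bind_cols(mvcs, combine_cluster_scores(d, s))
}

#' Normalise and combine cluster scores into weights
#'
#' The normalisation/combination step on its own: min-max normalises the
#' mean log-likelihoods `d` and sizes `s` across the candidate set and
#' returns the geometric-mean weights with the positivity floor.
#'
#' @param d Numeric vector of per-cluster mean NB log-likelihoods.
#' @param s Numeric vector of cluster sizes (same length).
#' @return Tibble with columns `d_bar`, `s_bar`, `w`.
#' @examples
#' combine_cluster_scores(c(-100, -50, -10), c(1000, 2000, 3000))
#' @export
combine_cluster_scores <- function(d, s) {
  stopifnot(length(d) == length(s))
  d_bar <- minmax_unit(d)
  s_bar <- minmax_unit(as.numeric(s))
  tibble(d_bar = d_bar, s_bar = s_bar,
         w = pmax(sqrt(d_bar * s_bar), MVS_WEIGHT_FLOOR))
}

# total NB log-likelihood of one sample's depths (zero depths included);
# an all-zero sample is a point mass at zero, log-likelihood 0
sample_nb_loglik <- function(x) {
  if (all(x == 0)) return(0)
  withCallingHandlers(
    fit_negative_binomial(x)$log_likelihood,
    message = function(m) invokeRestart("muffleMessage"))
}

minmax_unit <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Score table in the TSV interchange layout
#'
#' @param scored A scored cluster tibble from [score_clusters()].
#' @return A tibble with columns `epsilon`, `min_points`, `cluster_index`,
#'   `size`, `d`, `d_bar`, `s_bar`, `w`.
#' @export
cluster_scores <- function(scored) {
  dplyr::select(scored, "epsilon", "min_points", "cluster_index",
                size = "n_loci", "d", "d_bar", "s_bar", "w")
}
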