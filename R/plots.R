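#' Candidate-cluster score map
#'
#' Scatter of cluster size against mean NB log-likelihood `d`, sized by
#' the combined weight `w` and coloured by the clustering parameters;
#' clusters selected as independent-set members (and, when available,
#' those surviving the MVS filters) are highlighted.
#'
#' @param object An `mvs_set` from [mvs_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvs_set
#' @export
autoplot.mvs_set <- function(object, ...) {
  sc <- dplyr::select(object$clusters, -"loci")
  sc$status <- dplyr::case_when(
    sc$cluster_id %in% object$selection$mvs$cluster_id ~ "MVS",
    sc$cluster_id %in% object$mwis$cluster_id ~ "independent set",
    TRUE ~ "candidate")
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$n_loci, y = .data$d)) +
    ggplot2::geom_point(ggplot2::aes(
      size = .data$w, colour = factor(.data$epsilon),
      shape = .data$status)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cluster size (metavariants)",
                  y = "mean NB log-likelihood d",
                  colour = "epsilon", shape = NULL, size = "w") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise F_ST matrix
#'
#' @param fst A symmetric pairwise F_ST matrix (sample ids as dimnames),
#'   e.g. one `pairwise` element of an `mvs_popgen` result.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_pairwise_fst <- function(fst, title = NULL) {
  df <- as_tibble(as.table(fst), .name_repair = ~ c("s1", "s2", "fst"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s1, y = .data$s2,
                                   fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$fst)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "F_ST", title = title) +
    ggplot2::theme_minimal()
}

#' LK distribution against its neutral chi-square expectation
#'
#' Histogram of per-locus Lewontin-Krakauer statistics for one or all
#' MVSs with the chi-square(m - 1) density overlaid; under neutral
#' evolution of most loci the two should agree, and the upper-tail
#' excess is what the selection scan flags.
#'
#' @param popgen An `mvs_popgen` result.
#' @param m Number of samples used (degrees of freedom + 1).
#' @param mvs_id Optional single MVS id; default pools all.
#' @return A ggplot object.
#' @export
plot_lk <- function(popgen, m, mvs_id = NULL) {
  tl <- tidy(popgen)
  if (!is.null(mvs_id)) tl <- tl[tl$mvs_id == mvs_id, , drop = FALSE]
  xs <- seq(0.01, max(tl$lk, qchisq(0.999, m - 1)), length.out = 200)
  dens <- tibble(lk = xs, y = stats::dchisq(xs, df = m - 1))
  ggplot2::ggplot(tl, ggplot2::aes(x = .data$lk)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey70") +
    ggplot2::geom_line(data = dens, ggplot2::aes(y = .data$y),
                       colour = "firebrick") +
    ggplot2::labs(x = "LK", y = "density") +
    ggplot2::theme_minimal()
}
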