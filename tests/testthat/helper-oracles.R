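# Independent reference implementations used as oracles. These stay
# deliberately naive (full distance matrices, exhaustive enumeration) and
# share no code with the package internals.

# Brute-force DBSCAN facts from the full distance matrix: which points are
# core, the partition of core points into density-connected components,
# and the noise set. Border assignment is order-dependent in DBSCAN, so
# the oracle reports, for each non-core non-noise point, the set of
# adjacent core components it may legally join.
dbscan_bruteforce <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  dmat <- as.matrix(dist(x))
  nb <- dmat <= eps                     # closed ball, diagonal TRUE
  core <- rowSums(nb) >= min_pts
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      reach <- which(core & nb[p, ] & is.na(comp))
      comp[reach] <- cid
      queue <- c(queue, reach)
    }
  }
  border_opts <- lapply(seq_len(n), function(i) {
    if (core[i]) return(integer(0))
    sort(unique(comp[core & nb[i, ]]))
  })
  noise <- !core & vapply(border_opts, length, 1L) == 0
  list(core = core, comp = comp, noise = noise, border_opts = border_opts)
}

# checks a labelling against the brute-force facts (up to label permutation)
expect_dbscan_matches_oracle <- function(labels, oracle) {
  expect_equal(unname(which(labels == 0)), unname(which(oracle$noise)))
  core_idx <- which(oracle$core)
  if (length(core_idx) > 0) {
    # core partition must match exactly up to relabelling (bijection)
    tab <- table(oracle$comp[core_idx], labels[core_idx])
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
    expect_true(all(labels[core_idx] > 0))
  }
  border <- which(!oracle$core & !oracle$noise)
  for (i in border) {
    legal <- unique(stats::na.omit(
      labels[oracle$core][oracle$comp[oracle$core] %in%
                            oracle$border_opts[[i]]]))
    expect_true(labels[i] %in% legal)
  }
}

# Exhaustive maximum-weight independent set for graphs of <= 20 vertices,
# by vectorised bitmask enumeration.
mwis_exhaustive <- function(adj, w) {
  n <- length(w)
  stopifnot(n <= 20)
  masks <- 0:(2^n - 1)
  ok <- rep(TRUE, length(masks))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (adj[i, j]) {
        both <- bitwAnd(masks, bitwShiftL(1L, i - 1L) +
                          bitwShiftL(1L, j - 1L)) ==
          bitwShiftL(1L, i - 1L) + bitwShiftL(1L, j - 1L)
        ok <- ok & !both
      }
    }
  }
  weight <- rep(0, length(masks))
  for (i in seq_len(n)) {
    has <- bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0
    weight[has] <- weight[has] + w[i]
  }
  max(weight[ok])
}

# random overlap-style graph with strictly positive weights
random_weighted_graph <- function(n, p_edge = 0.35) {
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        adj[i, j] <- adj[j, i] <- runif(1) < p_edge
      }
    }
  }
  w <- runif(n, 0.01, 1)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::set_vertex_attr(g, "name",
                               value = sprintf("v%02d", seq_len(n)))
  g <- igraph::set_vertex_attr(g, "weight", value = w)
  list(g = g, adj = adj, w = w)
}

# 2-D grid-search oracle for the NB maximum likelihood (mu, size)
nb_loglik_grid <- function(counts, mu_hat, size_hat) {
  mus <- seq(0.7 * mu_hat, 1.3 * mu_hat, length.out = 81)
  sizes <- exp(seq(log(0.3 * size_hat), log(3 * size_hat), length.out = 121))
  best <- -Inf
  arg <- c(NA, NA)
  for (s in sizes) {
    lls <- vapply(mus, function(m)
      sum(dnbinom(counts, size = s, mu = m, log = TRUE)), 0)
    k <- which.max(lls)
    if (lls[k] > best) {
      best <- lls[k]
      arg <- c(mus[k], s)
    }
  }
  list(loglik = best, mu = arg[1], size = arg[2])
}

# small two-species planted dataset used across tests
small_two_species_sim <- function(seed = 7, n_loci = 300) {
  specs <- list(
    species_spec("spA", n_loci, c(50, 45, 12, 10, 11),
                 strain_fractions = c(0.1, 0.3, 0.5, 0.7, 0.9)),
    species_spec("spB", n_loci, c(11, 12, 48, 52, 50),
                 strain_fractions = c(0.2, 0.35, 0.5, 0.65, 0.8)))
  simulate_mvs_dataset(specs, seed = seed,
                       sample_ids = paste0("s", 1:5))
}
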