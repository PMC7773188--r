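cluster_tbl <- function(sets, w) {
  tibble::tibble(
    cluster_id = names(sets), epsilon = 1, min_points = 1L,
    cluster_index = seq_along(sets),
    n_loci = lengths(sets), loci = unname(sets),
    d = 0, d_bar = 1, s_bar = 1, w = w)
}

test_that("overlap edges follow the shared-locus rule", {
  tb <- cluster_tbl(list(a = c("1", "2", "3"), b = c("3", "4", "5"),
                         c = c("7", "8")), w = c(0.5, 0.6, 0.7))
  g <- build_overlap_graph(tb)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
  edge <- igraph::as_edgelist(g)
  expect_setequal(as.vector(edge), c("a", "b"))
})

test_that("duplicate locus sets merge keeping the heavier cluster", {
  tb <- cluster_tbl(list(a = c("1", "2"), b = c("2", "1"), c = c("2", "9")),
                    w = c(0.3, 0.8, 0.5))
  g <- build_overlap_graph(tb)
  expect_setequal(igraph::V(g)$name, c("b", "c"))
  expect_equal(igraph::V(g)$weight[igraph::V(g)$name == "b"], 0.8)
})

test_that("graph adjacency equals all-pairs intersection testing", {
  sim <- small_two_species_sim(seed = 23)
  m <- filter_loci(as_metavar_records(sim), 10, 10000, 5)
  mvcs <- run_mdbscan(m, c(10, 14, 18), c(4, 8), min_cluster_size = 20)
  scored <- score_clusters(mvcs, m)
  g <- build_overlap_graph(scored)
  nm <- igraph::V(g)$name
  sets <- scored$loci[match(nm, scored$cluster_id)]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i == j) next
      expect_equal(adj[i, j],
                   length(intersect(sets[[i]], sets[[j]])) > 0)
    }
  }
})

test_that("the greedy rule reproduces the hand-simulated examples", {
  # edgeless graph: everything is selected
  tb <- cluster_tbl(list(a = "1", b = "2", c = "3"), w = c(0.2, 0.9, 0.1))
  expect_equal(wmin_select(build_overlap_graph(tb)), c("a", "b", "c"))

  # path a-b-c, weights (1, 10, 1): b wins, neighbours deleted
  path <- cluster_tbl(list(a = c("x", "y"), b = c("y", "z"), c = c("z", "t")),
                      w = c(1, 10, 1))
  expect_equal(wmin_select(build_overlap_graph(path)), "b")

  # 4-cycle, weights (5, 1, 5, 1): f-tie between n1 and n3 broken by the
  # smaller identifier; node 3 survives to the next iteration
  cyc <- cluster_tbl(list(n1 = c("a", "d"), n2 = c("a", "b"),
                          n3 = c("b", "c"), n4 = c("c", "d")),
                     w = c(5, 1, 5, 1))
  expect_equal(wmin_select(build_overlap_graph(cyc)), c("n1", "n3"))
})

test_that("selection is an independent set meeting the weight bound", {
  withr::local_seed(77)
  for (trial in 1:60) {
    n <- sample(4:15, 1)
    rg <- random_weighted_graph(n)
    sel <- wmin_select(rg$g)
    idx <- match(sel, igraph::V(rg$g)$name)
    # independence
    if (length(idx) > 1) {
      expect_false(any(rg$adj[idx, idx]))
    }
    # Sakai bound: total weight >= sum w / (deg + 1) on the input graph
    deg <- rowSums(rg$adj)
    expect_gte(sum(rg$w[idx]), sum(rg$w / (deg + 1)) - 1e-12)
    # never above the exhaustive optimum
    expect_lte(sum(rg$w[idx]), mwis_exhaustive(rg$adj, rg$w) + 1e-12)
  }
})

test_that("greedy equals the optimum on edgeless graphs and resolves stars", {
  withr::local_seed(78)
  # edgeless: everything selected, trivially optimal
  rg <- random_weighted_graph(8, p_edge = 0)
  sel <- wmin_select(rg$g)
  expect_equal(sum(rg$w[match(sel, igraph::V(rg$g)$name)]),
               mwis_exhaustive(rg$adj, rg$w))
  # star: the only independent outcomes are the centre alone or all leaves
  n <- 7
  adj <- matrix(FALSE, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- TRUE
  for (trial in 1:10) {
    w <- runif(n, 0.1, 1)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    g <- igraph::set_vertex_attr(g, "name", value = paste0("v", 1:n))
    g <- igraph::set_vertex_attr(g, "weight", value = w)
    sel <- wmin_select(g)
    expect_true(identical(sel, "v1") ||
                  identical(sel, paste0("v", 2:n)))
    expect_gte(sum(w[match(sel, paste0("v", 1:n))]),
               sum(w / (rowSums(adj) + 1)) - 1e-12)
  }
})

test_that("selected clusters have pairwise disjoint locus sets", {
  sim <- small_two_species_sim(seed = 23)
  m <- filter_loci(as_metavar_records(sim), 10, 10000, 5)
  mvcs <- run_mdbscan(m, c(10, 14, 18), c(4, 8), min_cluster_size = 20)
  scored <- score_clusters(mvcs, m)
  mwis <- get_mwis(scored)
  expect_gt(nrow(mwis), 0)
  expect_equal(anyDuplicated(unlist(mwis$loci)), 0)
})
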