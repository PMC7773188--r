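truth_tbl <- function(labels) {
  tibble::tibble(locus_id = names(labels), species = unname(labels))
}

test_that("clusters are assigned by plurality with lexicographic ties", {
  truth <- truth_tbl(c(l1 = "A", l2 = "A", l3 = "A", l4 = "B", l5 = "B",
                       l6 = "B"))
  # 90/10-style majority
  a <- assign_clusters(list(c1 = c("l1", "l2", "l3", "l4")), truth)
  expect_equal(a$species, "A")
  expect_false(a$tie)
  # 50/50 tie -> lexicographically first label, tie flagged
  expect_message(
    t2 <- assign_clusters(list(c1 = c("l1", "l4")), truth), "tie")
  expect_equal(t2$species, "A")
  expect_true(t2$tie)
})

test_that("assignments equal a brute-force count-table argmax", {
  withr::local_seed(61)
  species <- c("A", "B")
  truth <- truth_tbl(setNames(sample(species, 60, TRUE), paste0("l", 1:60)))
  clusters <- list(c1 = paste0("l", 1:20), c2 = paste0("l", 21:45),
                   c3 = paste0("l", 46:60))
  a <- suppressMessages(assign_clusters(clusters, truth))
  lookup <- setNames(truth$species, truth$locus_id)
  for (i in seq_along(clusters)) {
    counts <- table(lookup[clusters[[i]]])
    expect_equal(a$species[i],
                 sort(names(counts)[counts == max(counts)])[1])
  }
})

test_that("per-cluster metrics reproduce the worked example", {
  # TP 55, FP 5, FN 45
  truth <- truth_tbl(setNames(
    c(rep("A", 100), rep("B", 20)), paste0("l", 1:120)))
  cluster <- c(paste0("l", 1:55), paste0("l", 101:105))
  met <- cluster_metrics(cluster, "A", truth)
  expect_equal(met$tp, 55)
  expect_equal(met$fp, 5)
  expect_equal(met$fn, 45)
  expect_equal(met$recall, 0.55, tolerance = 1e-6)
  expect_equal(met$precision, 55 / 60, tolerance = 1e-6)
  expect_equal(met$stn, 0.55 / (1 - 55 / 60), tolerance = 1e-6)
  expect_equal(met$stn, 6.6, tolerance = 1e-6)
  # integer identity
  expect_equal(met$recall * (met$tp + met$fn), met$tp)
})

test_that("perfect and empty-overlap clusters hit the metric extremes", {
  truth <- truth_tbl(setNames(rep(c("A", "B"), each = 10),
                              paste0("l", 1:20)))
  pure <- cluster_metrics(paste0("l", 1:10), "A", truth)
  expect_equal(pure$recall, 1)
  expect_equal(pure$precision, 1)
  expect_equal(pure$stn, Inf)
  none <- cluster_metrics(paste0("l", 11:20), "A", truth)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_equal(none$stn, 0)
})

test_that("purity and entropy match the printed formulas", {
  truth <- truth_tbl(setNames(
    c(rep("A", 14), rep("B", 6)), paste0("l", 1:20)))
  clusters <- list(q1 = paste0("l", c(1:9, 15)),       # A:9 B:1
                   q2 = paste0("l", c(10:14, 16:20)))  # A:5 B:5
  g <- clustering_metrics(clusters, truth)
  expect_equal(g$purity, 14 / 20, tolerance = 1e-6)
  ent1 <- -(0.9 * log2(0.9) + 0.1 * log2(0.1))
  expect_equal(g$entropy, ent1 + 1, tolerance = 1e-6)
  expect_equal(g$entropy, 1.469, tolerance = 1e-3)

  # single fully mixed cluster
  mixed <- clustering_metrics(list(q = paste0("l", c(1:5, 15:19))), truth)
  expect_equal(mixed$purity, 0.5)
  expect_equal(mixed$entropy, 1)

  # perfect clustering
  perfect <- clustering_metrics(
    list(a = paste0("l", 1:14), b = paste0("l", 15:20)), truth)
  expect_equal(perfect$purity, 1)
  expect_equal(perfect$entropy, 0)
})

test_that("purity ignores cluster order; entropy adds over clusters", {
  withr::local_seed(62)
  truth <- truth_tbl(setNames(sample(c("A", "B", "C"), 90, TRUE),
                              paste0("l", 1:90)))
  clusters <- split(paste0("l", 1:90), rep(1:3, each = 30))
  names(clusters) <- paste0("q", 1:3)
  g1 <- clustering_metrics(clusters, truth)
  g2 <- clustering_metrics(rev(clusters), truth)
  expect_equal(g1, g2)
  # merging two pure same-species clusters leaves both metrics unchanged
  pure <- list(a = paste0("l", 1:10), b = paste0("l", 11:20))
  truth_pure <- truth_tbl(setNames(rep("A", 20), paste0("l", 1:20)))
  merged <- list(ab = paste0("l", 1:20))
  expect_equal(clustering_metrics(pure, truth_pure),
               clustering_metrics(merged, truth_pure))
})

test_that("weighted entropy variant scales by cluster share", {
  truth <- truth_tbl(setNames(c(rep("A", 9), "B", rep("A", 5), rep("B", 5)),
                              paste0("l", 1:20)))
  clusters <- list(q1 = paste0("l", 1:10), q2 = paste0("l", 11:20))
  unweighted <- clustering_metrics(clusters, truth)$entropy
  weighted <- clustering_metrics(clusters, truth, weighted = TRUE)$entropy
  ent1 <- -(0.9 * log2(0.9) + 0.1 * log2(0.1))
  expect_equal(unweighted, ent1 + 1, tolerance = 1e-9)
  expect_equal(weighted, 0.5 * ent1 + 0.5, tolerance = 1e-9)
})

test_that("loci missing from the truth table are excluded with a message", {
  truth <- truth_tbl(c(l1 = "A", l2 = "A"))
  expect_message(
    a <- assign_clusters(list(c1 = c("l1", "l2", "zz")), truth),
    "absent")
  expect_equal(a$n_labelled, 2L)
})
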