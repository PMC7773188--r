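fmat <- function(..., samples = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("l", seq_len(nrow(m)))
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else
    samples
  m
}

test_that("allele frequency is the a-allele read share", {
  counts <- list(
    counts_a = matrix_to_tibble(fmat(c(10, 7, 0))),
    counts_b = matrix_to_tibble(fmat(c(0, 7, 0))))
  f <- allele_frequencies(counts)
  expect_equal(unlist(f[1, -1], use.names = FALSE), c(1, 0.5, NA))
})

test_that("global F_ST matches hand arithmetic", {
  gf <- global_fst(fmat(c(0.2, 0.4, 0.6)))
  # p_bar 0.4, population variance 0.02667, denominator 0.24
  expect_equal(gf$per_locus$fst, 0.08 / 3 / 0.24, tolerance = 1e-12)
  expect_equal(gf$per_locus$fst, 1 / 9, tolerance = 1e-9)

  expect_equal(global_fst(fmat(c(0, 1)))$per_locus$fst, 1)
  expect_equal(global_fst(fmat(c(0.3, 0.3, 0.3)))$per_locus$fst, 0)
})

test_that("monomorphic loci get F_ST 0 and stay out of the mean", {
  gf <- global_fst(fmat(c(0, 0, 0), c(0.2, 0.4, 0.6)))
  expect_equal(gf$per_locus$fst, c(0, 1 / 9), tolerance = 1e-9)
  expect_equal(gf$mean_fst, 1 / 9, tolerance = 1e-9)
})

test_that("loci with fewer than two defined samples are excluded", {
  f <- fmat(c(0.5, NA, NA), c(0.2, 0.4, 0.6))
  expect_message(gf <- global_fst(f), "excluded")
  expect_equal(gf$per_locus$locus_id, "l2")
})

test_that("F_ST stays within [0, 1] and ignores allele polarity", {
  withr::local_seed(51)
  f <- matrix(runif(500 * 6), ncol = 6,
              dimnames = list(paste0("l", 1:500), paste0("s", 1:6)))
  gf <- global_fst(f)
  expect_true(all(gf$per_locus$fst >= 0 & gf$per_locus$fst <= 1))
  flip <- f
  flip[3, ] <- 1 - flip[3, ]
  expect_equal(global_fst(flip)$per_locus$fst, gf$per_locus$fst)
  expect_equal(pairwise_fst(flip), pairwise_fst(f))
})

test_that("LK and its p-values follow the chi-square reference", {
  lk <- lk_statistic(fst = c(0.2), mean_fst = 0.2, m = 7)
  expect_equal(lk$lk, 6)

  expect_equal(lk_statistic(0, 0.1, 5)$p_value, 1)

  q95 <- qchisq(0.95, df = 4)
  lk2 <- lk_statistic(q95 * 0.1 / 4, 0.1, 5)
  expect_equal(lk2$lk, q95, tolerance = 1e-9)
  expect_equal(lk2$p_value, 0.05, tolerance = 1e-9)

  expect_error(lk_statistic(0.1, 0, 5), "mean F_ST")
})

test_that("outlier calling thresholds on the p-value", {
  tl <- tibble::tibble(locus_id = c("a", "b", "c"),
                       p_value = c(0.04, 0.05, 0.2))
  expect_equal(selection_outliers(tl, 0.05), c("a", "b"))
  expect_equal(selection_outliers(tl, 0.001), character(0))
})

test_that("neutral simulation calibrates the LK chi-square tail", {
  withr::local_seed(53)
  n <- 5000
  m <- 7
  nu <- 200
  mu <- runif(n, 0.2, 0.8)
  f <- matrix(rbeta(n * m, shape1 = rep(mu * nu, m),
                    shape2 = rep((1 - mu) * nu, m)), ncol = m)
  rownames(f) <- paste0("l", seq_len(n))
  colnames(f) <- paste0("s", seq_len(m))
  gf <- global_fst(f)
  lk <- lk_statistic(gf$per_locus$fst, gf$mean_fst, m)
  rate <- mean(lk$p_value <= 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(rate - 0.05), 2 * se)
})

test_that("pairwise F_ST matches the per-pair estimator", {
  f <- fmat(c(0.1, 0.9), c(0.5, 0.5), c(0.3, 0.7))
  pw <- pairwise_fst(f)
  # per-locus pair estimates: 0.64, 0 (informative), 0.16 -> mean 0.2667
  expect_equal(pw["s1", "s2"], (0.64 + 0 + 0.16) / 3, tolerance = 1e-9)
  expect_equal(diag(pw), c(s1 = 0, s2 = 0))
  expect_equal(pw, t(pw))

  # identical columns give zero differentiation
  same <- fmat(c(0.2, 0.2), c(0.8, 0.8))
  expect_equal(pairwise_fst(same)["s1", "s2"], 0)
})

test_that("mvs_popgen wires statistics per MVS and tidies", {
  sim <- small_two_species_sim(seed = 37, n_loci = 300)
  m <- filter_loci(as_metavar_records(sim), 10, 10000, 5)
  res <- suppressMessages(mvs_pipeline(
    m, eps_values = c(12, 16), p_values = c(5, 10),
    min_cluster_size = 100, m_min2 = 50L))
  expect_gt(nrow(res$selection$mvs), 0)
  pg <- res$popgen
  tl <- tidy(pg)
  expect_true(all(c("mvs_id", "fst", "lk", "p_value", "outlier") %in%
                    names(tl)))
  one <- pg[[1]]
  expect_equal(one$per_locus$lk,
               (5 - 1) * one$per_locus$fst / one$mean_fst)
  expect_equal(dim(one$pairwise), c(5, 5))
  g <- glance(pg)
  expect_equal(nrow(g), length(pg))
})
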