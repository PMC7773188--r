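test_that("invalid species specifications fail with the field named", {
  expect_error(species_spec("x", 0, c(10, 20), strain_fractions = c(.1, .2)),
               "n_loci")
  expect_error(species_spec("x", 10, c(10, -2), strain_fractions = c(.1, .2)),
               "coverage_means")
  expect_error(species_spec("x", 10, c(10, 20), strain_fractions = c(.1)),
               "strain_fractions")
  expect_error(species_spec("x", 10, c(10, 20),
                            strain_fractions = c(.1, 1.4)),
               "strain_fractions")
  expect_error(species_spec("x", 10, c(10, 20), nb_dispersion = 0,
                            strain_fractions = c(.1, .2)),
               "nb_dispersion")
  expect_error(simulate_mvs_dataset(list(), seed = 1), "at least one")
})

test_that("the same seed reproduces bit-identical matrices", {
  specs <- six_species_community(n_loci = 50)
  a <- simulate_mvs_dataset(specs, seed = 99)
  b <- simulate_mvs_dataset(specs, seed = 99)
  expect_identical(a$matrices$coverage, b$matrices$coverage)
  expect_identical(a$matrices$counts_a, b$matrices$counts_a)
  expect_identical(a$freq_true, b$freq_true)
  c <- simulate_mvs_dataset(specs, seed = 100)
  expect_false(identical(a$matrices$coverage, c$matrices$coverage))
})

test_that("depths follow the requested NB moments", {
  spec <- species_spec("x", 10000, c(30, 30), nb_dispersion = 5,
                       strain_fractions = c(0.5, 0.5))
  sim <- simulate_mvs_dataset(list(spec), seed = 7)
  depth <- tibble_to_matrix(sim$matrices$coverage)
  for (j in 1:2) {
    expect_equal(mean(depth[, j]), 30, tolerance = 0.02 * 30)
    expect_equal(var(depth[, j]), 30 + 30^2 / 5,
                 tolerance = 0.1 * (30 + 30^2 / 5))
  }
})

test_that("allele counts split depth binomially at the strain fraction", {
  spec <- species_spec("x", 5000, c(40, 40), strain_fractions = c(0.5, 0.5))
  sim <- simulate_mvs_dataset(list(spec), seed = 8)
  a <- tibble_to_matrix(sim$matrices$counts_a)
  b <- tibble_to_matrix(sim$matrices$counts_b)
  depth <- tibble_to_matrix(sim$matrices$coverage)
  expect_equal(a + b, depth)
  expect_equal(mean(b / depth, na.rm = TRUE), 0.5, tolerance = 0.01)

  # asymmetric fraction: the derived allele (count_b) carries it
  spec2 <- species_spec("y", 5000, c(40, 40), strain_fractions = c(0.2, 0.8))
  sim2 <- simulate_mvs_dataset(list(spec2), seed = 8)
  b2 <- tibble_to_matrix(sim2$matrices$counts_b)
  d2 <- tibble_to_matrix(sim2$matrices$coverage)
  expect_equal(colMeans(b2 / d2, na.rm = TRUE),
               c(metaG1 = 0.2, metaG2 = 0.8), tolerance = 0.02)
})

test_that("true pairwise differentiation is monotone in the gradient gap", {
  specs <- six_species_community(n_loci = 10)
  sim <- simulate_mvs_dataset(specs, seed = 3)
  f <- tibble_to_matrix(sim$freq_true)[sim$truth$species == "sp1", ]
  pw <- pairwise_fst(f)
  # along the monotone gradient, differentiation grows with distance
  expect_true(all(diff(pw[1, 2:7]) > 0))
  expect_gt(pw["metaG1", "metaG7"], pw["metaG3", "metaG5"])
})

test_that("truth labels cover every locus and match block sizes", {
  specs <- six_species_community(n_loci = 25)
  sim <- simulate_mvs_dataset(specs, seed = 4)
  expect_equal(nrow(sim$truth), nrow(sim$matrices$coverage))
  expect_equal(unname(table(sim$truth$species)[paste0("sp", 1:6)]),
               rep(25L, 6), ignore_attr = TRUE)
})

test_that("non-polymorphic loci share one frequency across samples", {
  spec <- species_spec("x", 400, c(30, 30, 30),
                       strain_fractions = c(0.1, 0.5, 0.9),
                       polymorphic_fraction = 0.5)
  sim <- simulate_mvs_dataset(list(spec), seed = 21)
  f <- tibble_to_matrix(sim$freq_true)
  constant <- apply(f, 1, function(r) max(r) - min(r) < 1e-12)
  expect_gt(mean(constant), 0.35)
  expect_lt(mean(constant), 0.65)
  gradient <- f[!constant, , drop = FALSE]
  expect_true(all(abs(sweep(gradient, 2, c(0.1, 0.5, 0.9))) < 1e-12))
})
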