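#' Specification of one simulated species
#'
#' Describes the matrix-level statistical signature one species leaves in
#' multi-sample metagenomic variant data: per-sample negative-binomial
#' depth of coverage (the abundance profile that density-based clustering
#' exploits), and a two-strain admixture whose derived-strain proportion
#' per sample sets the true allele frequency at every polymorphic locus.
#'
#' @param name Species label used in the truth table.
#' @param n_loci Number of variable loci (>= 1).
#' @param coverage_means Positive per-sample mean depths (the abundance
#'   profile), length = sample count.
#' @param nb_dispersion NB size/dispersion parameter `r` of the depths
#'   (variance `mu + mu^2 / r`), default 5.
#' @param strain_fractions Per-sample derived-strain proportion in
#'   \[0, 1\], length = sample count; the true frequency of the derived
#'   allele at every polymorphic locus.
#' @param polymorphic_fraction Fraction of loci carrying the strain
#'   difference (default 1). The remainder are shared polymorphisms with a
#'   per-locus constant frequency drawn from Beta(2, 2).
#' @param freq_jitter_sd Standard deviation of optional per-locus
#'   logit-scale jitter around the strain fraction (default 0, none).
#' @return An object of class `mvs_species_spec`.
#' @export
species_spec <- function(name, n_loci, coverage_means, nb_dispersion = 5,
                         strain_fractions, polymorphic_fraction = 1,
                         freq_jitter_sd = 0) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort("invalid `name`: need one non-empty string")
  }
  if (!is.numeric(n_loci) || length(n_loci) != 1 || n_loci < 1) {
    abort(paste0("invalid `n_loci` for species ", name, ": need >= 1"))
  }
  if (any(coverage_means <= 0)) {
    abort(paste0("invalid `coverage_means` for species ", name,
                 ": all must be > 0"))
  }
  if (nb_dispersion <= 0) {
    abort(paste0("invalid `nb_dispersion` for species ", name))
  }
  if (length(strain_fractions) != length(coverage_means)) {
    abort(paste0("invalid `strain_fractions` for species ", name,
                 ": length must match `coverage_means`"))
  }
  if (any(strain_fractions < 0 | strain_fractions > 1)) {
    abort(paste0("invalid `strain_fractions` for species ", name,
                 ": need values in [0, 1]"))
  }
  if (polymorphic_fraction <= 0 || polymorphic_fraction > 1) {
    abort(paste0("invalid `polymorphic_fraction` for species ", name,
                 ": need a value in (0, 1]"))
  }
  structure(list(name = name, n_loci = as.integer(n_loci),
                 coverage_means = as.numeric(coverage_means),
                 nb_dispersion = nb_dispersion,
                 strain_fractions = as.numeric(strain_fractions),
                 polymorphic_fraction = polymorphic_fraction,
                 freq_jitter_sd = freq_jitter_sd),
            class = "mvs_species_spec")
}

#' Reference six-species, seven-sample community
#'
#' The package's standard simulated community: six bacterial species in a
#' seven-sample admixture. Each species is abundant (mean depth 60x times
#' a species scale) in a distinct triple of samples and at baseline (12x
#' times the scale) elsewhere; the triples are lines of the Fano plane, so
#' any two species share exactly one abundant sample and profiles stay
#' mutually distinguishable even in five-sample subsets. Species-specific
#' scale factors (1-1.9) stagger overall abundances so that different
#' clustering parameter cells pick up different species. Every species is
#' an admixture of an ancestral and a derived strain with the derived
#' fraction increasing monotonically from the first to the last sample,
#' at species-specific rates.
#'
#' @param n_loci Variable loci per species, default 2000.
#' @param nb_dispersion NB dispersion of depths, default 5.
#' @return List of six [species_spec()] objects.
#' @export
six_species_community <- function(n_loci = 2000, nb_dispersion = 5) {
  triples <- list(c(1, 2, 3), c(1, 4, 5), c(2, 4, 6),
                  c(2, 5, 7), c(3, 4, 7), c(3, 5, 6))
  # scale-to-pattern assignment keeps species whose patterns lose contrast
  # in sample subsets far apart in overall abundance
  scales <- c(1.32, 1.5, 1.0, 1.9, 1.7, 1.15)
  gradients <- list(
    c(0.05, 0.20, 0.35, 0.50, 0.65, 0.80, 0.95),
    c(0.10, 0.23, 0.37, 0.50, 0.63, 0.77, 0.90),
    c(0.04, 0.16, 0.28, 0.40, 0.52, 0.64, 0.76),
    c(0.12, 0.24, 0.36, 0.48, 0.60, 0.72, 0.84),
    c(0.08, 0.15, 0.25, 0.38, 0.52, 0.66, 0.80),
    c(0.06, 0.18, 0.32, 0.46, 0.60, 0.74, 0.88))
  purrr::map(1:6, function(i) {
    mu <- rep(12, 7)
    mu[triples[[i]]] <- 60
    species_spec(paste0("sp", i), n_loci = n_loci,
                 coverage_means = mu * scales[i],
                 nb_dispersion = nb_dispersion,
                 strain_fractions = gradients[[i]])
  })
}

#' Simulate a multi-species metavariant dataset
#'
#' Draws, for every species and sample, locus depths from
#' `NB(mu = coverage_means[j], size = nb_dispersion)` and splits each
#' depth binomially into derived- and ancestral-allele read counts using
#' the species' per-sample strain fraction (the derived-allele count is
#' `count_b`, so the tracked `a`-allele frequency is `1 - fraction`).
#' The seed fully determines the output.
#'
#' @param species List of [species_spec()] objects (>= 1), all with the
#'   same number of samples (>= 2).
#' @param seed Integer seed.
#' @param sample_ids Optional sample names; default `metaG1..metaGm`.
#' @return An object of class `mvs_sim`: list with `matrices` (an
#'   unfiltered `mvs_matrices` object), `truth` (tibble `locus_id`,
#'   `species`), `freq_true` (wide tibble of true derived-allele
#'   frequencies), `specs`, `seed`.
#' @export
simulate_mvs_dataset <- function(species, seed, sample_ids = NULL) {
  if (inherits(species, "mvs_species_spec")) species <- list(species)
  if (length(species) < 1) abort("need at least one species spec")
  ok <- purrr::map_lgl(species, inherits, "mvs_species_spec")
  if (!all(ok)) abort("`species` must be a list of species_spec objects")
  m <- length(species[[1]]$coverage_means)
  if (m < 2) abort("need at least 2 samples")
  if (!all(purrr::map_int(species, ~ length(.x$coverage_means)) == m)) {
    abort("all species must have the same number of samples")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("metaG", seq_len(m))

  withr::with_seed(seed, {
    per_species <- purrr::map(species, function(sp) {
      n <- sp$n_loci
      depth <- sapply(sp$coverage_means, function(mu)
        rnbinom(n, mu = mu, size = sp$nb_dispersion))
      depth <- matrix(depth, nrow = n)
      poly <- stats::runif(n) <= sp$polymorphic_fraction
      f <- matrix(rep(sp$strain_fractions, each = n), nrow = n)
      if (any(!poly)) {
        shared <- rbeta(sum(!poly), 2, 2)
        f[!poly, ] <- matrix(rep(shared, m), ncol = m)
      }
      if (sp$freq_jitter_sd > 0) {
        jit <- stats::rnorm(n, sd = sp$freq_jitter_sd)
        f <- stats::plogis(stats::qlogis(pmin(pmax(f, 1e-9), 1 - 1e-9)) + jit)
      }
      cb <- matrix(rbinom(n * m, size = as.vector(depth),
                          prob = as.vector(f)), nrow = n)
      list(depth = depth, ca = depth - cb, cb = cb, f = f,
           species = rep(sp$name, n))
    })
    depth <- do.call(rbind, purrr::map(per_species, "depth"))
    ca <- do.call(rbind, purrr::map(per_species, "ca"))
    cb <- do.call(rbind, purrr::map(per_species, "cb"))
    f <- do.call(rbind, purrr::map(per_species, "f"))
    truth_species <- unlist(purrr::map(per_species, "species"))
    locus_ids <- sprintf("mv%06d", seq_len(nrow(depth)))
    dimnames(depth) <- dimnames(ca) <- dimnames(cb) <- dimnames(f) <-
      list(locus_ids, sample_ids)

    matrices <- new_mvs_matrices(
      coverage = depth, counts_a = ca, counts_b = cb,
      freq = ifelse(depth > 0, ca / ifelse(depth > 0, depth, 1), NA_real_),
      params = list(min_cum_depth = 0, max_cum_depth = Inf, min_samples = 1))
    structure(
      list(matrices = matrices,
           truth = tibble(locus_id = locus_ids, species = truth_species),
           freq_true = matrix_to_tibble(f),
           specs = species, seed = seed),
      class = "mvs_sim")
  })
}

#' @export
print.mvs_sim <- function(x, ...) {
  cat(sprintf("<mvs_sim> %d loci x %d samples, %d species (seed %s)\n",
              nrow(x$matrices$coverage), length(sample_ids(x$matrices)),
              length(x$specs), format(x$seed)))
  invisible(x)
}

#' @export
as_metavar_records.mvs_sim <- function(x) {
  as_metavar_records(x$matrices)
}

#' Write the truth table TSV
#'
#' @param x An `mvs_sim` dataset or a truth tibble.
#' @param path Output TSV path (columns `locus_id`, `species`).
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(x, path) {
  truth <- if (inherits(x, "mvs_sim")) x$truth else x
  readr::write_tsv(truth, path)
  invisible(path)
}
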