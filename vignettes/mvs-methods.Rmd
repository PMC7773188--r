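---
title: "Metavariant species: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metavariant species: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvspop)
```

## The metavariant species model

A *metavariant* is a biallelic single-nucleotide variant called directly
from raw multi-sample metagenomic reads, without a reference genome. All
that is known about it is, for each of the $m$ samples, the read counts
$c_a$ and $c_b$ supporting its two alleles. Its *locus* has depth of
coverage $c = c_a + c_b$, and the $n$ retained loci form the depth
matrix $L = (c_{ij}) \in \mathbb{N}^{n \times m}$.

A *metavariant species* (MVS) represents one biological species purely
by a set of intra-species metavariants. The working assumption, shared
with abundance-based contig binning, is that the depths of a species'
variable loci covariate across samples — the species' abundance profile
is a signature — so species emerge as clusters of the rows of $L$. The
allele frequencies $p = c_a / (c_a + c_b)$ of the clustered loci then
support standard population-genomic statistics without any reference.

The pipeline has six stages, each exposed as a tibble-in/tibble-out
function and chained by `mvs_pipeline()`:
`filter_loci()` → `run_mdbscan()` → `score_clusters()` →
`build_overlap_graph()`/`wmin_select()` → `select_mvs()` →
`mvs_popgen()`.

## Locus filtering

A locus is kept iff its cumulative depth $\sum_j c_{ij}$ lies in
$[a, b]$ and it *occurs* in at least $c$ samples. The package defines
occurrence as $c_{ij} > 0$, the simplest reading consistent with the
usual `-c m` invocation requiring presence in every sample; the
threshold is a parameter (`min_samples`) for callers who want a laxer
rule. Loci dropped earlier in parsing — multiallelic records,
non-substitutions, and loci whose source sequence carries more than one
variant — are counted and reported, never silently discarded, because
the fraction of complex bubbles is itself a useful quality signal.

The tracked frequency is that of allele $a$. Every downstream statistic
is symmetric under $p \mapsto 1 - p$, so the choice is inert; a
property-style test asserts this invariance.

## Multiple density-based clustering

DBSCAN with radius $\epsilon$ (Euclidean) and density threshold $p$
(minPts) is run on the rows of $L$: a locus is a core point iff its
closed $\epsilon$-ball holds at least $p$ loci; clusters are maximal
density-connected sets; the rest is noise. There is no optimal single
$(\epsilon, p)$ for heterogeneous communities — each species' cloud has
its own density — so a grid of values is run and all clusters with more
than 1,000 metavariants (strict inequality, configurable) are pooled
into one candidate set in which clusters from different runs overlap
freely. Resolving the overlaps is deferred to the independent-set stage.

Implementation notes:

* The $O(n^2)$ neighbourhood search and the expansion loop are in C++;
  neighbour lists are computed once per $\epsilon$ and shared across the
  $p$ grid.
* Border points reachable from two clusters join the first cluster that
  claims them in matrix row order, the classic DBSCAN order dependence
  made deterministic: with a fixed input ordering, results are
  bit-reproducible. A brute-force reference (distance matrix, core
  graph, BFS) is used by the tests to check the core partition and noise
  set exactly, and border assignments up to their legal ambiguity.
* `transform = "log1p"` clusters $\log(1 + c_{ij})$ instead of raw
  depths; the default is raw. Negative-binomial depths have standard
  deviation roughly proportional to the mean ($\mathrm{sd} \approx
  \mu/\sqrt{r}$ for large $\mu$), so on the raw scale abundant species
  form clouds whose spread rivals the separation between species, and no
  single Euclidean radius suits both a 20x and an 80x species. The log
  transform stabilises the variance (per-dimension spread
  $\approx \sqrt{1/\mu + 1/r}$, nearly scale-free), putting all species
  on one density scale; sub-unit $\epsilon$ values are the natural grid
  there. The reference benchmark uses it; raw-scale clustering remains
  appropriate for the shallower, Poisson-like depth distributions of
  read-simulator data.

## Cluster scoring

Sequencing depth of coverage is overdispersed relative to Poisson, so a
cluster that truly is one species should have, in each sample, depths
well fitted by a negative binomial. For each candidate cluster and each
sample, `fit_negative_binomial()` (method-of-moments start, numerical
MLE via fitdistrplus) returns the total log-likelihood at the optimum;
$d$ is the mean of these across samples. The likelihood is the total
over the cluster's loci — the literal fit likelihood — which couples $d$
to cluster size; the min-max normalisation below is therefore taken over
the whole candidate set so only relative position matters. Zero depths
are legitimate NB observations and are included; an all-zero sample
contributes log-likelihood 0 (a point mass at zero); underdispersed
input (variance ≤ mean) degenerates toward Poisson and returns a capped
dispersion with a note instead of failing.

Scores are combined as
$$\bar d = \frac{d - d_{\min}}{d_{\max} - d_{\min}}, \qquad
  \bar s = \frac{s - s_{\min}}{s_{\max} - s_{\min}}, \qquad
  w = \sqrt{\bar d \cdot \bar s},$$
the geometric mean balancing fit quality against size. Edge cases fixed
by convention: a single-candidate set (and any axis on which all
candidates tie) gets $\bar d = \bar s = 1$; and because min-max
necessarily sends one cluster to zero on each axis while the selection
algorithm requires strictly positive weights, $w$ is floored at
$10^{-6}$ (`MVS_WEIGHT_FLOOR`), preserving order among the floored while
keeping them dominated by everything else. An instructive side effect of
the normalisation: the giant low-quality cluster that DBSCAN produces at
over-large $\epsilon$ is usually both the largest and the worst-fitting
candidate, so it lands on the floor and never competes.

## Independent-set selection

Candidates form a weighted undirected graph: vertices are clusters with
weights $w$, and an edge joins two clusters iff their locus sets
intersect without being identical. Identical locus sets are merged
beforehand (keeping the higher weight) since they carry no information
and would only create ties. Selection is the greedy rule: repeat until
the graph is empty — (i) find connected components; (ii) in each
component take the vertex maximising $f(v) = w_v/(\deg v + 1)$;
(iii) delete it and its neighbours, keeping it in the output. The result
is an independent set whose weight is at least
$\sum_v w_v/(\deg v + 1)$ (Sakai's bound). Ties on $f$ break by higher
$w$, then lexicographically smaller cluster id, making selection
deterministic. Components are evaluated against the graph state at the
start of each outer iteration; $f$ is recomputed between iterations, not
within one.

The greedy rule is a heuristic, not an exact solver: tests verify
independence, the weight bound, and that it never exceeds the exhaustive
optimum on small graphs, but on stars (and many other graphs) it can
return the lighter of the two maximal independent sets — which is fine
for its purpose here, where same-species clusters from neighbouring grid
cells overlap heavily and any one of them is an acceptable
representative.

## MVS selection

A selected cluster is promoted to MVS by criteria applied in order:
strictly more than `k_min = 4` samples must show median cluster-locus
depth at least `c_m = 8` (allele frequencies below ~8x are too noisy to
trust); then, with per-sample median $\mathrm{med}_j$ and standard
deviation $\mathrm{sd}_j$ (sample sd, $n-1$) over the cluster's loci,
only loci with depth inside
$[\max(c_m,\ \mathrm{med}_j - 2\,\mathrm{sd}_j),\
   \mathrm{med}_j + 2\,\mathrm{sd}_j]$
in **every** sample are retained — the band keeps single-copy loci
matching the species' coverage signature and strips repeats and
mis-clustered loci; finally strictly more than `m_min2 = 100` loci must
survive. The per-sample reading of the band (rather than one pooled
band) is what makes "within bounds in all samples" meaningful when
abundances differ across samples; the lower bound is floored at $c_m$ so
every retained locus is usable for frequency estimation everywhere.
Clusters failing a criterion are dropped with a recorded reason.

## Population-genomic statistics

Per locus, across the samples with defined frequency:
$$F_{ST} = \frac{\mathrm{Var}(p)}{\bar p (1 - \bar p)},$$
with the population variance (divisor $m$), which bounds $F_{ST}$ in
$[0, 1]$ and matches the classic Lewontin–Krakauer formulation; the
sample-variance variant sits behind `var_type = "sample"`. Monomorphic
loci ($\bar p \in \{0, 1\}$) get $F_{ST} = 0$ and are excluded from the
across-loci mean $\bar F_{ST}$; loci with fewer than two defined
frequencies are excluded entirely, with a message.

The selection scan uses $LK = (m - 1)\, F_{ST} / \bar F_{ST}$, referred
to a $\chi^2_{m-1}$ distribution (upper tail); loci with
$p \le \alpha$ are flagged. The $\chi^2$ approximation holds when
differentiation is weak and frequencies are near-normal across samples;
the calibration test draws neutral frequencies per locus i.i.d. from a
Beta with concentration $\nu = 200$ (so $\bar F_{ST} \approx 1/(\nu+1)
\approx 0.005$, typical of weakly structured marine populations) and
checks the empirical 5% tail within two binomial standard errors at
5,000 loci. At strong differentiation or extreme frequencies the
approximation degrades — a property of the LK test itself, not of the
implementation.

Pairwise differentiation between samples restricts the same estimator to
each sample pair and averages per-locus values over the loci defined in
both and polymorphic within the pair (mirroring the monomorphic
exclusion above); `aggregate = "ratio"` provides the ratio-of-averages
alternative. The matrix is symmetric with zero diagonal.

## The synthetic community

The generator works at the variant-matrix level: it emulates the
statistical structure of a reference-free caller's output rather than
simulating reads. Per species and sample, locus depths are
$\mathrm{NB}(\mu_{j}, r)$; per locus, the true derived-allele frequency
equals the species' per-sample strain fraction, and the derived-allele
count is $\mathrm{Binomial}(c, f)$. All loci of a species share its
strain fractions (the two strains differ at every polymorphic site);
`polymorphic_fraction` and a logit-scale `freq_jitter_sd` relax this
behind flags. The seed fully determines the output.

`six_species_community()` fixes the reference conditions: six species,
seven samples, 2,000 loci per species, dispersion $r = 5$. Abundance
profiles place each species at 60x (times a species scale) in a distinct
triple of samples and 12x elsewhere; the triples are lines of the Fano
plane, so any two species share exactly one abundant sample and remain
distinguishable even after dropping samples. Species scales
(1.0–1.9) stagger overall abundance so different grid cells pick up
different species; the scale-to-pattern assignment deliberately gives
distant scales to species pairs whose patterns lose contrast in
five-sample subsets, keeping subset analyses well posed. Strain
gradients rise monotonically from sample 1 to 7 at species-specific
rates, giving each species a smooth differentiation gradient and making
the expected pairwise-$F_{ST}$ grow with inter-sample gradient distance.
At dispersion 5 the depth clouds are strongly overdispersed; the profile
contrast (five-fold between abundant and baseline levels) is what makes
the clouds separable on the log scale, satisfying the separation
premise the clustering stage needs. What the generator does **not**
emulate: sequencing error, caller artefacts, strain-level copy-number
variation, correlated depths along a genome, or more than two strains —
so passing benchmarks here demonstrate the statistical machinery, not
robustness to every failure mode of real data.

The benchmark driver `community_benchmark()` filters with
`-a 10 -b 500 -c m`, clusters the log-depths over
$\epsilon \in \{0.5, 0.6, 0.7, 0.8\} \cdot \sqrt{m/7}$ and
$p \in \{20, 40, 80\}$ (the $\sqrt{m/7}$ factor keeps the radius grid
calibrated when samples are dropped, since Euclidean distances grow with
the square root of the dimension), and applies all defaults downstream.
Differentiation accuracy is scored like a reference-based control: each
recovered MVS's pairwise-$F_{ST}$ matrix is compared entrywise with the
matrix from the loci truly belonging to the matched species, the same
coverage-band filter applied on both sides, and the maximum absolute
difference over all sample pairs and species is reported. Problem sizes
throughout (2,000 loci per species, ~11,000 after filtering, 5,000 loci
in the calibration study, 100-trial oracle comparisons) keep a full run
in tens of seconds on one core while leaving estimator noise well below
the tolerances being checked.

## Known limitations

* Two species whose abundance profiles covariate across all samples are
  indistinguishable to any abundance-based method; more samples is the
  only remedy. Recovery degrades gracefully with fewer samples —
  five samples still recover the six reference species one-to-one, but
  cluster precision dips below its seven-sample value, and the package
  makes no stronger claim.
* The greedy independent-set rule is approximate, and the weight score
  can in principle prefer a large merged cluster over two pure ones when
  the candidate set contains clusters of wildly different sizes;
  inspecting `tidy(res, "clusters")` (and `autoplot()`) for
  high-$\bar s$, low-$\bar d$ candidates is the practical safeguard.
* Without genotypes or haplotypes there are no $F_{ST}$ p-values,
  nucleotide diversity, or demographic inference; the LK scan is the
  package's only selection test and inherits the chi-square caveats
  above.
* DBSCAN's deterministic border assignment depends on input row order;
  identical matrices give identical results, but permuted input can move
  a handful of border loci between clusters.
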