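---
title: "Methods: measuring the sensitivity of genetic connectivity to sampling design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the sensitivity of genetic connectivity to sampling design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Site-based landscape genetics correlates pairwise genetic differentiation with
geographic or resistance distance. Classical estimators -- Weir-Cockerham
$\theta$ ($F_{ST}$), Jost's $D_{est}$, and the Euclidean distance between
allele-frequency vectors ($d_{eucl}$) -- are strictly *pairwise*: the estimate
for sites $A$ and $B$ uses only genotypes sampled at $A$ and $B$. Conditional
genetic distance (cGD), by contrast, is a *network* quantity: sites are nodes,
edges are retained only where the genetic covariance between two sites is
significant conditional on all other sites, and cGD is the shortest path
through the pruned network. cGD therefore depends on every site included in
the analysis -- which makes it potentially powerful (adding sites adds
information) and potentially fragile (sites you failed to sample distort it).

`popsens` implements both families of measures plus the machinery to quantify
that trade-off: subsampling experiments over sites and over individuals,
sensitivity statistics, a ground-truth gene-flow simulator on barrier cost
surfaces, and a calibrated synthetic-data generator. This vignette documents
the models, the defaults, and the design decisions taken where the methods
literature leaves genuine freedom.

# Pairwise estimators

**Weir-Cockerham $\theta$.** For each locus and allele we compute the
among-population ($a$), among-individual ($b$) and within-individual ($c$)
variance components for the two sites (two-population case, observed
heterozygosity included) and report the multilocus ratio
$\hat\theta = \sum a / \sum (a+b+c)$, summing components over alleles and loci
rather than averaging per-locus ratios. Negative estimates are reported as
computed -- clamping would silently break the variance-component identity.
An individual enters a locus only with both allele copies observed, because
$\theta$ needs genotypic heterozygosity.

**Jost's $D_{est}$.** Per locus, with two demes of (diploid-equivalent) sizes
$n_1, n_2$ and $\tilde n$ their harmonic mean,
$\hat H_S = \frac{2\tilde n}{2\tilde n - 1} H_S$,
$\hat H_T = H_T + \hat H_S / (4\tilde n)$, and
$D = 2\,(\hat H_T - \hat H_S)/(1 - \hat H_S)$.
Loci with $\hat H_S = 1$ are skipped (undefined ratio). The multilocus value
is the harmonic mean of the per-locus values truncated below at
$\varepsilon = 10^{-6}$ (harmonic means do not tolerate non-positive terms;
the truncation constant is exposed), with an arithmetic-mean alternative one
argument away since reference implementations do not document their choice.

**$d_{eucl}$.** The Euclidean norm of the difference between the two sites'
concatenated per-locus allele-frequency vectors; alleles unobserved at a site
count as frequency zero, loci with no data at either site are skipped. The
default is the raw norm; a Rogers-style per-locus $\tfrac12$-scaled average is
available via `scaling = "rogers"`.

Missing data for the frequency-based measures are handled gene-copy-wise: a
`0` allele code removes one gene copy from the denominator.

All three estimators are *local*: deleting every individual of any third site
leaves the $(A,B)$ entry identical to the last bit. This is tested as a
property and is the mechanism behind their exactly-zero relative error in the
unsampled-site experiment.

# The population graph and cGD

Construction follows the conditional-independence recipe for population
graphs:

1. Each individual is encoded as an allele-dosage vector (one column per
   observed allele per locus, entries allele count / 2). Missing genotypes
   receive the site-mean dosage, which keeps centroid algebra exact.
2. Site centroids are the per-site means; the among-site covariance is the
   double-centered squared centroid-distance matrix
   $C = -\tfrac12 H D^2 H$ -- equivalently, the covariance of the centered
   site centroids *across allele axes*.
3. $C$ is standardized to a correlation matrix, its (pseudo-)inverse gives
   partial correlations $\rho_{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$.
4. Each candidate edge is tested with the edge-exclusion deviance
   $-N \log(1-\rho_{ij}^2)$ against $\chi^2_{1,1-\alpha}$ (default
   $\alpha = 0.05$); all failing edges are removed in one shot.
5. Retained edges are weighted by the centroid Euclidean distance; cGD is the
   all-pairs shortest path. Site pairs in different components are undefined
   (`NA`) -- data, not an error -- and are dropped from any downstream mean,
   rank or Mantel computation.

Two numerical choices deserve emphasis, because they decide whether the graph
carries any conditional-independence information at realistic data sizes:

* **Deviance sample size.** The covariance in step 2 is estimated across the
  allele axes, so the default $N$ is the number of independent axes (dosage
  columns minus one compositional constraint per locus), not the number of
  genotyped individuals. With $N$ = individuals the $\chi^2$ threshold falls
  below the sampling noise of the partial correlations (for 15 loci with 10
  alleles, noise $\approx 1/\sqrt{135} \approx 0.09$, threshold
  $|\rho| > 0.09$ at $N = 450$), graphs saturate, and cGD collapses onto the
  direct centroid distances -- observable as mean cGD $\approx$ mean
  $d_{eucl}$, whereas sparse genuine networks give path sums well above the
  direct distances. The individuals-based reading remains available via
  `deviance_n = "individuals"`.
* **Shrinkage.** The correlation matrix is shrunk toward the identity with
  the Ledoit-Wolf/Schafer-Strimmer intensity estimated from the axes
  (`shrinkage = "auto"`), applied to the positive eigenvalues only so the
  null direction created by double-centering stays excluded from the
  precision. On cleanly structured data the estimated intensity is near zero
  and the procedure reduces to the plain pseudo-inverse; on strongly
  correlated, noisily estimated data it stabilizes the precision matrix. In
  validation on stepping-stone chains the default recovers all adjacent edges
  with few artifacts, and on weak-structure isolation-by-distance data of
  29-site scale it yields sparse graphs whose mean cGD is 2-3 times the mean
  $d_{eucl}$, the regime reported for real mustelid networks.

Pruning is one-shot. Stepwise backward elimination was considered and
rejected: a proper stepwise procedure requires refitting the Gaussian
graphical model after each removal, which is foreign to how population graphs
are computed in practice.

Double-centering always costs one rank, so the pseudo-inverse is the normal
path; a warning appears only if the rank drops further. A site whose centroid
coincides with the grand centroid makes the standardization in step 3
undefined; this is reported as an error. Note the practical corollary: data
in which sites are exchangeable draws around a common ancestor (no
between-site covariance structure) are *correctly* inferred to have few or no
significant conditional dependencies, and their graphs can be empty or
subdivided.

**Eigenvector centrality** uses the binary adjacency of the pruned graph,
computed per connected component and normalized to a maximum of 1 per
component, with non-negative scores; isolated nodes score 0. Edge weights are
distances (large = weakly connected), so weighting centrality by them would
invert its meaning; `weighted = TRUE` uses $1/w$ instead.

# Sensitivity statistics

* **Relative error**: $|{\rm estimate} - {\rm truth}|/|{\rm truth}| \times
  100$, undefined for zero truth (an error, not `NA`).
* **Cohen's d**: mean difference over the df-weighted pooled standard
  deviation; 0.2/0.5/0.8 read as small/medium/large.
* **Two-sample permutation test**: label permutations of the mean difference,
  two-sided by default, add-one rule $p = (1 + \#\,{\rm extreme})/(1 +
  n_{\rm perm})$ so $p \in (0, 1]$; default 9,999 permutations.
* **Spearman rank agreement**: over off-diagonal pairs defined in both
  matrices, average-rank ties; undefined below 3 common pairs.
* **Mantel test**: Pearson correlation of upper-triangle entries with
  undefined pairs excluded pairwise; significance by simultaneous row/column
  permutation, the permuted statistic computed under the same pairwise
  exclusion rule. With at most 7 sites all permutations are enumerated and
  the p-value is exact. One-sided for positive association by default --
  every isolation-by-distance/resistance use tests a positive relationship --
  with a two-sided alternative. Type-I error is verified by simulation to sit
  at $\alpha$ within $\pm 0.02$.
* **Bootstrap interval for Mantel r**: percentile interval over 10,000
  recomputations on 90% site subsamples drawn without replacement; degenerate
  draws are skipped and counted.

All randomized procedures take a seed and are bit-reproducible given it. No
multiple-testing correction is applied anywhere; contrasts are meant to be
chosen a priori.

# The two subsampling experiments

**Unsampled sites.** Sites are ranked by eigenvector centrality of the
full-data graph (components ordered by size, ties broken by site label). The
core is the $\lceil S/2 \rceil$ sites at one extreme; the other
$\lfloor S/2 \rfloor$ are removed and restored one per iteration
(most-to-least connected when restoring the least-connected half,
least-to-most when restoring the most-connected half). Every metric is
recomputed on the active dataset at each iteration but summarized only over
pairs among the fixed core, holding sample size constant; the truth is the
full-data value over the same pairs. Iteration 0 is the core alone; the final
iteration is the full dataset, so relative error is exactly 0 and Spearman
rho exactly 1 there by construction -- a convergence contract the tests
assert.

**Under-sampled sites.** Individuals are ranked by the absolute score on the
first principal component of the centered (unscaled) individual dosage
matrix: both extreme tails are "rare", scores near zero are "common"; the
eigenvector sign is fixed by making the largest-magnitude loading positive.
Per site, $\lfloor n/2 \rfloor$ individuals at the chosen extreme are
removed, then restored one per site per iteration in order of least-to-most
rare (or least-to-most common); exhausted sites simply stop receiving
individuals. The default cap rule limits the largest site's removals to the
second-largest removal count so that a single heavily sampled site does not
inflate the iteration count; explicit per-site caps may be supplied. Metrics
are summarized over *all* site pairs against the full-data truth.

Both protocols are deterministic given the dataset; only the per-iteration
Mantel permutations consume a (seeded, restored) random stream. Undefined
cGD pairs in subdivided networks are treated as missing, never as zero, and
subdivision events are visible through the per-iteration component count.

# The isolation-by-resistance simulator

The simulator provides a system where the process driving structure is known
with certainty, so the accuracy of a connectivity measure can be judged
against truth rather than against another estimate.

* **Surface.** A 7x7 grid of 5x5-unit cells; passable cells cost 1 per unit,
  nine cells are complete barriers, nine cells are populated sites in a 3x3
  arrangement (numbered row-major, so sites 4-6 form the middle row). The
  default layout places six barriers on the vertical inter-site segments and
  three in corners, so horizontal neighbours are 10 cost units apart,
  vertical neighbours 16 (detoured), and the top and bottom site rows are
  more than 25 units apart everywhere. Least-cost distances use 4-neighbour
  unit moves, each step paying the destination cell's cost (diagonal moves
  off; unit arithmetic stays integral). The layout is data (a CSV-round-trip
  `cost_surface`), not a constant.
* **Demography.** 450 fixed locations (two per unit cell of each site, one
  male and one female initially), uniformly random initial genotypes at 15
  loci with 10 possible alleles. Per generation: each adult dies with
  probability 0.5 (a `strict_nonoverlap` flag kills all adults instead, the
  stricter reading of non-overlapping generations); each surviving female
  mates with a uniformly drawn male within 3 cost units, males reusable; each
  pair produces 4 offspring with equiprobable sex; offspring settle in random
  order on vacant locations within 25 cost units of the natal location with
  probability proportional to $1/d^2$ (distances floored at 1 unit to keep
  the kernel finite at the natal location); unplaced offspring die; every
  allele copy mutates with probability 5e-4 to one of the other 9 states
  (k-allele model). 250 generations, 21 replicates. Sequential settlement
  means co-dispersing offspring compete for vacancies -- the documented
  contention contract.
* **Why this layout.** Under the 25-unit cap, dispersal between the top and
  bottom site rows is impossible, so the middle row is the sole conduit of
  top-bottom gene flow. Leaving sites 4-6 unsampled then removes exactly the
  nodes that mediate the resistance structure -- the scenario the
  `ibr_experiment()` conditions probe by building the network on the 6 core
  sites plus 0, 1 ({6}), 2 ({4,6}) or 3 ({4,5,6}) of the middle-row sites and
  correlating core-site cGD with log least-cost distance. A full-cell barrier
  costs +6 units to bypass, so 10/16 is the closest realizable contrast for
  adjacent sites on this cell geometry.

With the true migration topology imposed on the graphs, the all-sites
condition yields a tight, high Mantel correlation (about 0.87 +/- 0.05 across
replicates in our runs) versus roughly 0.5 for the core-only condition -- the
inclusion effect is intrinsic to these study conditions. With *estimated*
graphs the effect's measured size is limited by the variance of the partial
correlations across the ~135 allele axes the paper-scale genotypes provide;
averaging the among-site covariance across replicates recovers the migration
topology almost perfectly, so the estimator is unbiased but noisy at this
data size. The packaged default (axes-calibrated deviance plus auto
shrinkage) preserves the ordering of the inclusion conditions; the
spec-literal alternative (`deviance_n = "individuals"`, `shrinkage = "none"`)
saturates the graphs and erases the effect entirely.

# The synthetic generator

`generate_clustered()` is a hierarchical Dirichlet (F-model) generator:
ancestral per-locus frequencies from a symmetric Dirichlet; cluster
frequencies from ${\rm Dir}(\theta_{\rm cluster} \cdot p_{\rm anc})$; site
frequencies from ${\rm Dir}(\theta_{\rm site,i} \cdot p_{\rm cluster})$ with
$\theta_{\rm site,i}$ shrinking with distance from the cluster centroid
(`ibd_decay`); genotypes Hardy-Weinberg within sites. Sample sizes are
truncated-normal draws matching a target mean/SD/range, or an explicit
vector. The shipped presets (`marten_like`: 29 sites, 12 loci, K = 1, 11-47
individuals per site; `fisher_like`: 34 sites, 16 loci, K = 5, 7-48 per site)
carry concentrations calibrated once, on an independent seed grid, so the
mean pairwise $\theta$ matches the published summaries of the datasets they
emulate (0.022 and 0.068); the calibration is re-verified by the test suite,
and differentiation is monotone in the concentrations (also tested).

What the F-model does *not* emulate: between-site covariance. Given the
ancestor, K = 1 F-model sites are conditionally independent -- a star -- so a
population graph on such data is rightly near-empty. Real datasets show
isolation by distance, i.e. stepping-stone covariance, which
`generate_ibd()` provides: frequencies drift along the minimum spanning tree
of the site coordinates with per-edge Dirichlet concentration
$1/({\rm ibd\_decay} \times {\rm edge\ length})$, so divergence accumulates
with path distance. Tests that need genuine network structure (experiment
convergence, locality, rank trends) therefore use IBD data; tests of the
calibration targets use the presets. Passing tests on these generators show
the machinery is correct under the statistical shape they produce -- they say
nothing about linkage, null alleles, selection, or the demographic history of
any real population.

# Problem sizes and numerical conventions

The test suite runs the full 21-replicate, 250-generation simulation once
(about a minute), drift-chain graph checks at 6 sites x 80 loci, experiment
checks at 6-14 sites, a 1,000-replicate Mantel type-I calibration at 8 sites,
and 20-replicate convergence/calibration sweeps; the acceptance script
re-simulates the 21 replicates and recomputes the inclusion contrasts from
scratch. Other conventions: permutation p-values use the add-one rule;
Dirichlet draws come from normalized gamma variates with shapes floored at
1e-12; eigen-decompositions use a relative tolerance of
`sqrt(.Machine$double.eps)` for rank decisions; PCA and centrality
eigenvector signs are fixed (largest-magnitude loading positive; scores
non-negative); centrality ties break by site label; Genepop output is always
the 3-digit dialect, input accepts 2- or 3-digit.

# Known limitations

* gstudio-era software internals (exact covariance estimator, deviance
  degrees of freedom, stepwise vs one-shot pruning, edge weighting) are not
  printed anywhere authoritative; every such step here is explicit and
  config-surfaced, but other implementations may differ in detail.
* cGD magnitudes depend on the pruning configuration; comparisons should fix
  `alpha`, `shrinkage` and `deviance_n` across conditions (the experiment
  drivers do).
* The simulator is a minimal CDPOP-style model: no age structure, no
  per-individual fecundity variation, no sex-biased dispersal.
* Partial Mantel tests are intentionally out of scope.
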