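---
title: "Bootstrap confidence intervals for beta-diversity effect sizes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap confidence intervals for beta-diversity effect sizes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadivci)
```

## The question the package answers

Amplicon surveys of microbial communities (the motivating system is foliar
fungal endophytes, but nothing here is taxon-specific) summarize
between-group structure with a dissimilarity-based effect size: ANOSIM R or
PERMANOVA R². A point estimate alone hides how much that number depends on
three design variables the investigator controls:

* **sampling effort** — how many biological samples per comparison group;
* **sequencing depth** — how many reads are retained per sample;
* **taxonomic resolution** — the similarity cutoff at which reads are
  clustered into OTUs.

`betadivci` quantifies that dependence by bootstrap: for every cell of a
(effort × depth × resolution × metric × test) grid it draws many replicate
datasets, recomputes the effect size, and reports the mean with a 95%
percentile interval. A companion Wright–Fisher simulator asks the same
question about a purely stochastic signal: how deep must one sequence to
*detect* neutral drift between two communities?

## Effect sizes, from their definitions

Both statistics are implemented directly from their definitions and
cross-checked in the test suite against vegan as an independent reference.

**ANOSIM R.** All `M = N(N−1)/2` pairwise dissimilarities are ranked with
average ranks for ties, and

$$R = \frac{\bar r_B - \bar r_W}{M/2},$$

where $\bar r_B$ and $\bar r_W$ are the mean ranks of between-group and
within-group pairs. R is 1 under perfect separation and has mean exactly 0
over the permutation distribution of labels. Average ranks matter here:
bootstrap resampling *with replacement* duplicates samples and creates exact
zero-distance ties, which mid-ranks absorb without special cases.

**PERMANOVA.** With $SS_T = \frac1N \sum_{i<j} d_{ij}^2$ and
$SS_W = \sum_g \frac1{n_g}\sum_{i<j\in g} d_{ij}^2$, the among-group part is
$SS_A = SS_T - SS_W$, the effect size is $R^2 = SS_A/SS_T$, and
$\text{pseudo-}F = \frac{SS_A/(a-1)}{SS_W/(N-a)}$. On univariate Euclidean
data pseudo-F reduces to the classic one-way ANOVA F, which the tests assert
to 1e-8; the exact permutation mean of R² is $(a-1)/(N-1)$, asserted to
1e-12 by exhaustive enumeration. Only one-way designs are supported — the
analyses this package serves compare single factors.

**Permutation p-values** use uniform label permutations drawn with
replacement and the +1 correction $p = (1 + \#\{R^* \ge R\})/(1 + B)$, so
p is never 0. The $\ge$ uses a 1e-12 tolerance to keep results platform
stable. Degenerate inputs: all-identical samples ($SS_T = 0$) are an error;
$SS_W = 0$ with signal reports pseudo-F as `Inf` and R² as 1.

## Normalization and rarefaction

**Cumulative sum scaling (CSS).** Sample j's scaling factor is the sum of
its counts up to the `quantile_p` quantile of its *positive* counts, with
linear-interpolation (type 7) quantiles throughout — one fixed convention so
factors are bit-reproducible. The quantile is fixed at 0.5 by default and
configurable; adaptive per-dataset quantile selection is deliberately out of
scope. The scale constant (default 1000) is cosmetic: only relative
abundances reach the dissimilarities. CSS maps zeros to zeros, so binary
Jaccard is provably unchanged by it (a test asserts exact equality).

**Rarefaction** draws exactly `depth` reads per sample *without* replacement
(multivariate hypergeometric, computed by sequential conditional
hypergeometric draws in C++ against R's RNG). Samples shallower than the
target are dropped with a warning, never up-sampled. Retained columns sum to
`depth` exactly and never exceed their original counts — both hard
assertions in the tests.

## The sweep engine

Each replicate of a sweep cell applies, in order: (1) collapse to the
resolution level — resolution is a property of the table, so this happens
first and once; (2) rarefy to the cell's depth with a replicate-specific
derived seed; (3) CSS-normalize if the configuration says so; (4) draw
`effort` samples per group uniformly with replacement, keeping duplicates as
distinct units; (5) compute the dissimilarity matrix and the statistic.
Effort-only sweeps default to CSS; depth sweeps run on raw rarefied counts
(`renormalize_after_rarefy` re-enables CSS after rarefaction for anyone who
wants the other pairing, default off). Each of a cell's replicates rarefies
independently and then resamples — one rarefaction per replicate.

The cell summary is the arithmetic mean of the replicates (the point
estimate) with linear-interpolation percentile bounds at `ci_level` (default
95%). Cells that cannot run — for example a depth that no sample reaches —
are recorded as failed rows with the reason, so wide grids always complete.
Determinism: one master seed; every cell and replicate derives its own
stream by integer mixing, so identical configurations give bit-identical
results (asserted in the tests), independent of cell execution order.

`ci_width_decrease()` condenses a depth sweep into the average fractional
CI-width change between two depths over all matched cells, reported as a
percentage; cells with zero initial width are excluded with a warning.

## The neutral-drift simulator

A `community` is a census: integer abundances summing exactly to a fixed
population size (default 954 taxa, five million individuals, lognormal rank
abundance). One generation of drift is a single multinomial draw of the full
population with probabilities proportional to current abundances — the
Wright–Fisher model, which the phrase "resampling with replacement"
describes directly. No mutation, immigration, or selection: richness can
only fall, expected relative abundances are a martingale, and expected
heterozygosity decays by $(1 - 1/N)$ per generation. The tests verify the
martingale property and the decay law against their closed forms at
N = 1000.

`drift_experiment()` branches two independent drift trajectories from one
seed community (20 generations by default), then for every combination of
sequencing depth and samples-per-community draws multinomial read samples
from each drifted census and runs the ANOSIM permutation test on raw counts
— no normalization, no rarefaction: simulated reads need neither, and
leaving them untouched keeps the depth axis interpretable. Read sampling uses with-replacement (multinomial)
draws: at depths of at most 2% of a five-million census the difference from
hypergeometric sampling is negligible, and it keeps the sampler fast.
The reproduced pattern: drift is invisible at 100 reads per sample and
detected essentially always at 50,000 (~1% of the community), with detection
power monotone in depth.

## The synthetic-data generator

The package ships no real sequencing data; every analysis runs on synthetic
data whose structure mirrors published fungal-endophyte OTU tables:
10²–10³ taxa, long-tailed lognormal rank abundance,
per-sample depths of ~20,000 reads, and two-group designs spanning a strong
regime (two geographic populations, 14 + 24 samples) and a weak regime (two
tissue types, 60 + 60 samples).

The generative model: a lognormal base composition shared by all groups; a
group effect; per-sample lognormal compositional noise
(`sample_noise_sdlog`, default 0.8 — real within-group heterogeneity is
large); multinomial reads at fixed depth 20,000 (a negative-binomial option
exists because real per-sample depths vary, but fixed depths make
rarefaction tests exact). Random taxonomic hierarchies emulate re-clustering
at 99/97/95/90% cutoffs by merging a growing fraction of clusters; built by
merging the previous level's clusters, so refinement consistency holds by
construction.

Effect modes and the frozen presets:

* **specialist** multiplies a small set (12) of the most abundant taxa by
  $e^{\pm s}$ per group. Preset strengths were calibrated once by grid
  search against the regime bounds and frozen: `strong` uses s = 0.85
  (full-data ANOSIM R ≈ 0.8–0.95, PERMANOVA R² > 0.17 on CSS-normalized
  Bray-Curtis), `weak` uses s = 0.27 (R ≈ 0.13–0.26, R² < 0.05). The `null`
  preset shares the weak design with zero effect; strength 0 reduces every
  mode to it exactly.
* **rare_turnover** gives each group a disjoint subset of the rare tail
  (taxa below the median base abundance; `effect_strength` is the fraction
  involved). Two refinements proved necessary to reproduce the qualitative
  depth contrast — Bray-Curtis precision gaining more from depth than
  Jaccard while both effect sizes rise. First, the turnover taxa follow an
  abundance–occupancy relationship: the mass-carrying taxa just below the
  median are near-ubiquitous in their group (a stable abundance signal),
  while the numerous tiny ones are patchy. Second, a per-sample patchiness
  exponent makes samples differ in how much of their group's rare biosphere
  they carry, which keeps presence/absence structure — and hence Jaccard —
  noisy at any depth. Without these, clean disjoint presence sets of
  hundreds of detectable taxa drive binary Jaccard to a saturated R of 1
  with zero-width intervals, the opposite of the observed contrast. Frozen
  preset: sdlog 0.9, noise 0.25, occupancy floor 0.25, patchiness 1.4,
  strength 1.0, two groups of 20.

What the generator does *not* emulate: sequencing error, chimeras,
mistagging, contamination, spatial distance-decay among plots (multi-group
designs are exchangeable), or taxonomic signal in identifiers. Passing
tests on this generator show the *statistical machinery* behaves as the
theory predicts under a realistic abundance structure — they are not
evidence about any particular real dataset.

## Numerical choices

* Quantiles (CSS and percentile CIs): linear interpolation (R type 7),
  everywhere.
* Ranks: average ranks for ties.
* Seeds: one master integer seed per entry point; child streams derived by
  deterministic integer mixing (multiplicative congruential step, kept below
  2³¹); the caller's RNG state is always restored.
* The ≥ in permutation p-values carries a 1e-12 tolerance.
* Integer conservation: rarefied columns, collapsed tables, and drifting
  populations are conserved exactly, not to tolerance.
* Distance kernels and rarefaction run in C++ (Rcpp); both are exact
  implementations of the formulas above, not approximations.

## Problem sizes used in the checks

The shipped verification uses scaled designs chosen to exercise every code
path at desk scale: drift detectability over 20 seeded repetitions of the
full 954-taxon, five-million-individual community across depths
100–100,000 with 1000-permutation tests; effort sweeps over 20 seeded
repetitions of the strong preset across efforts 5–60 with 200 bootstrap
replicates per cell (the sweep machinery defaults to 1000, the convention
the package follows for real analyses); and the rare-turnover depth
contrast averaged over four seeded datasets and efforts {5, 10, 20}.

## Known limitations

* One-way designs only; no nested/blocked permutations, no PERMDISP
  companion test, no multiple-testing control across sweep cells.
* ANOSIM and PERMANOVA are the only effect sizes; Bray-Curtis and binary
  Jaccard the only metrics (no UniFrac — no phylogeny exists for synthetic
  taxa).
* Bootstrap-with-replacement resampling of small groups biases ANOSIM R
  upward slightly (duplicates create zero-distance within-group ties); this
  is inherent to the resampling design the package reproduces, and the CIs
  are percentile intervals of exactly that resampling distribution.
* CSS uses a fixed quantile, not the adaptive selection of the original
  normalization literature.
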