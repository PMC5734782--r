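# betadivci

Bootstrap confidence intervals for microbial beta-diversity effect sizes.

High-throughput amplicon surveys compare communities with
dissimilarity-based effect sizes — ANOSIM R and PERMANOVA R² on Bray-Curtis
or binary Jaccard distances — but a point estimate says nothing about how
much the answer depends on the study design. `betadivci` puts confidence
intervals on those effect sizes across the three design axes an investigator
controls: **sampling effort** (samples per group, resampled with
replacement), **sequencing depth** (rarefaction without replacement), and
**taxonomic resolution** (OTU-cluster collapsing). A Wright–Fisher
**neutral-drift simulator** asks the complementary question: how deep must
one sequence before two communities that differ only by drift become
distinguishable at all?

The statistics are implemented from first principles:

* ANOSIM: rank all M = N(N−1)/2 dissimilarities (average ranks for ties),
  then R = (r̄_B − r̄_W) / (M/2).
* PERMANOVA: SS_T = (1/N) Σ_{i<j} d²_ij, SS_W = Σ_g (1/n_g) Σ_{i<j∈g} d²_ij,
  R² = (SS_T − SS_W)/SS_T, pseudo-F = (SS_A/(a−1)) / (SS_W/(N−a));
  permutation p-values with the +1 correction.
* Every sweep cell is summarized by the mean of its bootstrap replicates
  with 95% percentile bounds.

A synthetic OTU-table generator (lognormal rank abundance, 10²–10³ taxa,
~20,000 reads/sample, calibrated strong/weak/null/rare-turnover presets)
makes the whole pipeline runnable and testable with no external data.
vegan's implementations are used in the test suite as independent
cross-checks, never as the computation.

## Worked example

```r
library(betadivci)

# a "strong" two-population dataset: 14 + 24 samples, 400 taxa, 20k reads
ds <- simulate_grouped_dataset(synthetic_preset("strong", seed = 1))

# full-data effect size: CSS-normalize, Bray-Curtis, ANOSIM permutation test
D   <- bray_curtis(css_normalize(ds$table))
fit <- permutation_test(D, ds$groups, test = "ANOSIM",
                        n_permutations = 1000, seed = 1)
fit
#> <effect_size_test> ANOSIM: R = 0.9363, p = 0.000999 (1000 permutations, 38 samples, 2 groups)

# how does precision depend on sampling effort?
cfg <- sweep_config(effort_grid = c(5, 10, 20), n_boot = 200,
                    metric = "bray-curtis", test = "ANOSIM", seed = 1)
run_sweep(ds$table, ds$groups, cfg)
#>     test      metric resolution depth effort n_boot  mean lower upper  width
#> 1 ANOSIM bray-curtis         NA    NA      5    200 0.940 0.788 1.000 0.2120
#> 2 ANOSIM bray-curtis         NA    NA     10    200 0.940 0.852 0.992 0.1403
#> 3 ANOSIM bray-curtis         NA    NA     20    200 0.935 0.886 0.977 0.0916
```

The mean effect size is stable (~0.94) while the 95% interval narrows from
0.21 to 0.09 as effort grows from 5 to 20 samples per group: more samples
buy precision, not a different answer. The same engine sweeps rarefaction
depths (`depth_grid`) and hierarchy levels (`resolution_levels`), and
`autoplot()` draws the trends.

Drift detectability — two communities drifted 20 generations from one
954-taxon, five-million-individual census, compared at increasing depth on
raw counts:

```r
comm <- lognormal_community(n_taxa = 954, population_size = 5e6, seed = 1)
drift_experiment(comm, generations = 20, depth_grid = c(100, 5000, 50000),
                 n_samples_grid = 20, n_permutations = 1000, seed = 1)
#>   depth n_samples      metric statistic  p_value
#> 1   100        20 bray-curtis    0.0292 0.183816
#> 2  5000        20 bray-curtis    0.1426 0.000999
#> 3 50000        20 bray-curtis    0.8715 0.000999
```

At 100 reads/sample the drifted communities are indistinguishable
(R ≈ 0.03, p > 0.05); at 50,000 reads — about 1% of the census — they
separate almost completely (R ≈ 0.87). Purely stochastic community
divergence lives in the rare tail, and only deep sequencing sees it.

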