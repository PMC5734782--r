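Package: betadivci
Title: Confidence Intervals for Beta-Diversity Effect Sizes Across
    Sampling Effort, Sequencing Depth, and Taxonomic Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bootstrap confidence-interval analysis of community
    dissimilarity effect sizes (ANOSIM R and PERMANOVA R-squared) for
    microbial count tables.  Provides cumulative-sum-scaling
    normalization and rarefaction, Bray-Curtis and binary Jaccard
    dissimilarities, permutation tests implemented from their
    definitions, a sweep engine that resamples groups with replacement
    across grids of sampling effort, rarefied sequencing depth, and
    taxonomic resolution and summarizes each cell as a percentile
    confidence interval, a neutral-drift (Wright-Fisher) community
    simulator for depth-dependent detectability experiments, and a
    synthetic OTU-table generator that emulates long-tailed fungal
    endophyte communities for fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
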