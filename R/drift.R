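#' Construct a census community
#'
#' A community is a fully-censused population: a vector of absolute taxon
#' abundances summing exactly to a fixed population size.  The taxon list is
#' fixed for the lifetime of the community — drift can drive taxa to zero,
#' but no new taxa ever arise (no diversification, no migration).
#'
#' @param abundances Non-negative integer vector, optionally named with taxon
#'   identifiers.
#' @return A list of class `community` with `taxon_ids`, `abundances`,
#'   `population_size`.
#' @export
community <- function(abundances) {
  if (anyNA(abundances) || any(abundances < 0) ||
      any(abundances != round(abundances))) {
    abort("abundances must be non-negative integers")
  }
  ids <- names(abundances) %||% paste0("taxon_", seq_along(abundances))
  structure(
    list(taxon_ids = ids,
         abundances = as.double(unname(abundances)),
         population_size = sum(as.double(abundances))),
    class = "community"
  )
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> %d taxa (%d extant), %s individuals\n",
              length(x$abundances), sum(x$abundances > 0),
              format(x$population_size, big.mark = ",")))
  invisible(x)
}

#' Evolve a community by neutral drift
#'
#' Wright-Fisher drift: each generation, the whole population of
#' `population_size` individuals is replaced by a multinomial draw of the
#' same size with probabilities proportional to current abundances (sampling
#' parents with replacement).  Population size is conserved exactly every
#' generation; relative abundances are a martingale (no selection); taxa hit
#' by drift stay at zero forever.
#'
#' @param comm A [community()].
#' @param generations Number of generations (>= 0; 0 returns the community
#'   unchanged).
#' @param seed Integer seed; trajectories are deterministic given `seed`.
#' @return The drifted [community()].
#' @export
drift_generations <- function(comm, generations, seed = 1L) {
  if (generations < 0) abort("generations must be >= 0")
  if (generations == 0) return(comm)
  ab <- with_seed(seed, {
    ab <- comm$abundances
    n <- comm$population_size
    for (t in seq_len(generations)) {
      alive <- ab > 0
      if (sum(alive) <= 1) break  # absorbing state: a single surviving taxon
      draw <- rmultinom(1, size = n, prob = ab[alive])[, 1]
      ab[alive] <- draw
    }
    ab
  })
  out <- comm
  out$abundances <- as.double(ab)
  stopifnot(sum(out$abundances) == out$population_size)
  out
}

#' Sample sequencing reads from a census community
#'
#' Draws `n_samples` independent read samples of `depth` reads each from the
#' community's relative abundances (multinomial, i.e. with replacement — at
#' depths of at most a few percent of the census size this is
#' indistinguishable from without-replacement sampling).
#'
#' @param comm A [community()].
#' @param depth Reads per sample, between 1 and the population size.
#' @param n_samples Number of samples to draw.
#' @param seed Integer seed.
#' @param prefix Prefix for the generated sample identifiers.
#' @return A [count_table()] with one column per sample; every column sums to
#'   `depth`.
#' @export
sample_community <- function(comm, depth, n_samples, seed = 1L,
                             prefix = "s") {
  if (depth < 1 || depth > comm$population_size) {
    abort("depth must be in [1, population_size]")
  }
  x <- with_seed(seed,
                 rmultinom(n_samples, size = depth, prob = comm$abundances))
  dimnames(x) <- list(comm$taxon_ids, paste0(prefix, seq_len(n_samples)))
  count_table(x)
}

#' Richness and heterozygosity of a community
#'
#' Richness is the number of taxa with positive abundance; heterozygosity is
#' Gini-Simpson diversity `1 - sum(p_i^2)` on relative abundances.  Under
#' Wright-Fisher drift the expected heterozygosity decays by a factor
#' `(1 - 1/N)` per generation.
#'
#' @param comm A [community()].
#' @return Named list with `richness` and `heterozygosity`.
#' @export
community_stats <- function(comm) {
  p <- comm$abundances / comm$population_size
  list(richness = sum(comm$abundances > 0),
       heterozygosity = 1 - sum(p^2))
}

#' Drift-detectability experiment across sequencing depths
#'
#' Reproduces the design of the simulated-drift analysis: two communities are
#' drifted independently for `generations` generations from one seed
#' community; for every combination of sequencing depth and number of samples
#' per community, read samples are drawn from each drifted community, a
#' dissimilarity matrix is computed on the raw counts (no normalization, no
#' rarefaction), and an ANOSIM permutation test asks whether the two drifted
#' communities are distinguishable.
#'
#' @param seed_community A [community()] (e.g. [lognormal_community()] with
#'   954 taxa and five million individuals).
#' @param generations Drift generations for each community (default 20).
#' @param depth_grid Sequencing depths to test (default the simulated-drift
#'   grid 100 ... 100,000).
#' @param n_samples_grid Samples drawn per community (default `c(5, 10, 15, 20)`).
#' @param metric Dissimilarity metric for the comparison.
#' @param n_permutations Permutations for the ANOSIM test (default 1000).
#' @param seed Master integer seed; the two drift trajectories branch into
#'   independent streams derived from it.
#'
#' @return A tibble of class `drift_experiment` with one row per
#'   (depth, n_samples) cell: `depth`, `n_samples`, `metric`, `statistic`
#'   (ANOSIM R), `p_value`.
#' @export
drift_experiment <- function(seed_community,
                             generations = 20,
                             depth_grid = c(100, 1000, 5000, 10000, 50000, 100000),
                             n_samples_grid = c(5, 10, 15, 20),
                             metric = c("bray-curtis", "jaccard"),
                             n_permutations = 1000,
                             seed = 1L) {
  metric <- match.arg(metric)
  comm_a <- drift_generations(seed_community, generations,
                              seed = mix_seed(seed, 1L))
  comm_b <- drift_generations(seed_community, generations,
                              seed = mix_seed(seed, 2L))
  grid <- tidyr::expand_grid(depth = depth_grid, n_samples = n_samples_grid)
  rows <- purrr::pmap(c(grid, list(.cell = seq_len(nrow(grid)))),
    function(depth, n_samples, .cell) {
      ta <- sample_community(comm_a, depth, n_samples,
                             seed = mix_seed(seed, .cell, 3L), prefix = "A_")
      tb <- sample_community(comm_b, depth, n_samples,
                             seed = mix_seed(seed, .cell, 4L), prefix = "B_")
      x <- cbind(unclass(ta), unclass(tb))
      gm <- tibble::tibble(
        sample_id = colnames(x),
        group = rep(c("A", "B"), each = n_samples)
      )
      keep <- rowSums(x) > 0  # taxa absent from every read sample carry no signal
      D <- dissimilarity(count_table(x[keep, , drop = FALSE]), metric)
      fit <- permutation_test(D, gm, test = "ANOSIM",
                              n_permutations = n_permutations,
                              seed = mix_seed(seed, .cell, 5L))
      tibble::tibble(statistic = fit$statistic, p_value = fit$p_value)
    })
  out <- dplyr::bind_cols(grid, metric = metric, dplyr::bind_rows(rows))
  class(out) <- c("drift_experiment", class(out))
  out
}
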