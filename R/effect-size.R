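#' ANOSIM R statistic
#'
#' Analysis of similarities: all M = N(N-1)/2 pairwise dissimilarities are
#' ranked (ties get average ranks), and
#' `R = (rbar_B - rbar_W) / (M / 2)`
#' contrasts the mean rank of between-group pairs against within-group
#' pairs.  R is 1 when every between-group dissimilarity exceeds every
#' within-group one, and 0 in expectation under exchangeable labels.
#' Average ranks keep the statistic well-defined when bootstrap resampling
#' duplicates samples (exact zero-distance ties).
#'
#' @param D A [stats::dist] of pairwise dissimilarities among samples.
#' @param groups Group assignments for the samples in `D` (data frame with
#'   `sample_id`/`group` columns, or named vector); at least two groups with
#'   at least two samples each.
#' @return The ANOSIM R statistic, a number in \[-1, 1\].
#' @export
anosim_r <- function(D, groups) {
  pp <- prepare_pairs(D, groups)
  r <- rank(pp$d)  # average ranks for ties
  anosim_r_from_ranks(r, pp$g, pp$ii, pp$jj)
}

anosim_r_from_ranks <- function(r, g, ii, jj) {
  within <- g[ii] == g[jj]
  m <- length(r)
  (mean(r[!within]) - mean(r[within])) / (m / 2)
}

#' One-way PERMANOVA from a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: the total sum of squared
#' dissimilarities `SS_T = (1/N) sum_{i<j} d_ij^2` is partitioned into a
#' within-group part `SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2` and the
#' among-group remainder `SS_A = SS_T - SS_W`.  The effect size is
#' `R2 = SS_A / SS_T` and the test statistic is
#' `pseudo_F = (SS_A / (a - 1)) / (SS_W / (N - a))` for `a` groups and `N`
#' samples.  With Euclidean distances on univariate data, `pseudo_F` equals
#' the classic one-way ANOVA F exactly.
#'
#' @inheritParams anosim_r
#' @return A list with `pseudo_F`, `R2`, `SS_A`, `SS_W`, `SS_T`,
#'   `n_samples`, `n_groups`.  If `SS_W` is 0 with `SS_A > 0`, `pseudo_F`
#'   is `Inf` and `R2` is 1.
#' @export
permanova <- function(D, groups) {
  pp <- prepare_pairs(D, groups)
  permanova_from_d2(pp$d^2, pp$g, pp$ii, pp$jj, pp$n_per_group)
}

permanova_from_d2 <- function(d2, g, ii, jj, n_per_group) {
  n <- length(n_per_group) # not group count; fix below
  N <- sum(n_per_group)
  a <- length(n_per_group)
  ss_t <- sum(d2) / N
  if (ss_t <= 0) abort("all samples identical (SS_T = 0); PERMANOVA undefined")
  within <- g[ii] == g[jj]
  if (any(within)) {
    ss_by_group <- rowsum(d2[within], group = g[ii][within])
    ng <- n_per_group[rownames(ss_by_group)]
    ss_w <- sum(ss_by_group[, 1] / ng)
  } else {
    ss_w <- 0
  }
  ss_a <- ss_t - ss_w
  if (ss_w <= 0) {
    f <- if (ss_a > 0) Inf else NaN
    r2 <- if (ss_a > 0) 1 else 0
  } else {
    f <- (ss_a / (a - 1)) / (ss_w / (N - a))
    r2 <- ss_a / ss_t
  }
  list(pseudo_F = f, R2 = r2, SS_A = ss_a, SS_W = ss_w, SS_T = ss_t,
       n_samples = N, n_groups = a)
}

#' Permutation test for ANOSIM or PERMANOVA
#'
#' The observed statistic (ANOSIM R, or PERMANOVA pseudo-F with its R2) is
#' compared against the null distribution obtained by randomly permuting
#' group labels.  Permutations are drawn uniformly with replacement from the
#' permutation group, and the p-value uses the +1 correction
#' `p = (1 + #\{perm stat >= observed\}) / (1 + n_permutations)`,
#' so p is never exactly zero.  The >= comparison uses a 1e-12 tolerance to
#' avoid floating-point order artifacts.
#'
#' @inheritParams anosim_r
#' @param test `"ANOSIM"` or `"PERMANOVA"`.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed; the permutation stream is deterministic given
#'   `seed`.  The observed statistic never depends on it.
#' @return An object of class `effect_size_test`; see [tidy.effect_size_test()].
#' @export
permutation_test <- function(D, groups, test = c("ANOSIM", "PERMANOVA"),
                             n_permutations = 1000, seed = 1L) {
  test <- match.arg(test)
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  pp <- prepare_pairs(D, groups)
  N <- sum(pp$n_per_group)

  if (test == "ANOSIM") {
    r <- rank(pp$d)
    observed <- anosim_r_from_ranks(r, pp$g, pp$ii, pp$jj)
    stat_fun <- function(g) anosim_r_from_ranks(r, g, pp$ii, pp$jj)
    statistic <- observed
    pseudo_F <- NA_real_
    R2 <- NA_real_
  } else {
    d2 <- pp$d^2
    obs <- permanova_from_d2(d2, pp$g, pp$ii, pp$jj, pp$n_per_group)
    stat_fun <- function(g) {
      permanova_from_d2(d2, g, pp$ii, pp$jj, pp$n_per_group)$pseudo_F
    }
    observed <- obs$pseudo_F
    statistic <- obs$R2
    pseudo_F <- obs$pseudo_F
    R2 <- obs$R2
  }

  perm_stats <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    stat_fun(pp$g[sample.int(N)])
  }, numeric(1)))
  p <- (1 + sum(perm_stats >= observed - 1e-12)) / (1 + n_permutations)

  structure(
    list(test = test, statistic = statistic, pseudo_F = pseudo_F, R2 = R2,
         p_value = p, n_permutations = n_permutations,
         n_samples = N, n_groups = length(pp$n_per_group),
         permutation_stats = perm_stats),
    class = "effect_size_test"
  )
}

#' @export
print.effect_size_test <- function(x, ...) {
  cat(sprintf("<effect_size_test> %s: %s = %.4f, p = %.4g (%d permutations, %d samples, %d groups)\n",
              x$test,
              if (x$test == "ANOSIM") "R" else "R2",
              x$statistic, x$p_value, x$n_permutations, x$n_samples,
              x$n_groups))
  if (x$test == "PERMANOVA") cat(sprintf("  pseudo-F = %.4f\n", x$pseudo_F))
  invisible(x)
}

#' Tidy an effect-size permutation test
#'
#' @param x An `effect_size_test` from [permutation_test()].
#' @param ... Unused.
#' @return One-row tibble with columns `test`, `statistic`, `pseudo_F`,
#'   `R2`, `p_value`, `n_permutations`, `n_samples`, `n_groups`.
#' @export
tidy.effect_size_test <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic,
                 pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
                 n_permutations = x$n_permutations,
                 n_samples = x$n_samples, n_groups = x$n_groups)
}

#' @rdname tidy.effect_size_test
#' @export
glance.effect_size_test <- function(x, ...) tidy(x)

# Align a dist object with group labels and precompute the pair index
# vectors for the lower triangle (column-major: pair (ii[k], jj[k]), ii > jj).
prepare_pairs <- function(D, groups) {
  if (!inherits(D, "dist")) abort("D must be a 'dist' object")
  labels <- attr(D, "Labels")
  N <- attr(D, "Size")
  if (is.null(labels)) labels <- as.character(seq_len(N))
  gm <- as_group_map(groups)
  g <- setNames(gm$group, gm$sample_id)[labels]
  if (anyNA(g)) {
    abort(paste0("samples in D missing from groups: ",
                 paste(head(labels[is.na(g)], 5), collapse = ", ")))
  }
  n_per_group <- table(g)
  used <- n_per_group[n_per_group > 0]
  if (length(used) < 2) abort("need at least two groups")
  if (any(used < 2)) {
    abort(paste0("group(s) with fewer than two samples: ",
                 paste(names(used)[used < 2], collapse = ", ")))
  }
  jj <- rep.int(seq_len(N - 1), times = (N - 1):1)
  ii <- sequence((N - 1):1, from = 2:N)
  list(d = as.numeric(D), g = unname(g), ii = ii, jj = jj,
       n_per_group = c(table(g)))
}
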