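test_that("ANOSIM R matches hand-ranked values and perfect separation", {
  # 2+2 design: within {0.1, 0.6}, between {0.2, 0.3, 0.4, 0.5} -> R = 0
  D <- dist_from_lower(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                       c("a1", "a2", "b1", "b2"))
  g <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_equal(anosim_r(D, g), 0)

  # every between distance above every within distance -> R = 1
  x <- matrix(c(10, 0, 11, 0, 0, 10, 0, 12), nrow = 2,
              dimnames = list(c("t1", "t2"), c("a1", "a2", "b1", "b2")))
  D2 <- bray_curtis(count_table(x))
  expect_equal(anosim_r(D2, g), 1)

  # inverted structure: within pairs farther than between pairs -> R < 0
  D3 <- dist_from_lower(c(0.9, 0.2, 0.3, 0.4, 0.5, 0.8),
                        c("a1", "a2", "b1", "b2"))
  expect_lt(anosim_r(D3, g), 0)
})

test_that("ANOSIM agrees with vegan and handles duplicate samples", {
  skip_if_not_installed("vegan")
  for (seed in 1:5) {
    tab <- random_table(n_taxa = 30, n_samples = 10, seed = seed)
    gm <- two_group_map(colnames(tab))
    D <- bray_curtis(tab)
    ref <- vegan::anosim(D, gm$group, permutations = 0)
    expect_equal(anosim_r(D, gm), unname(ref$statistic), tolerance = 1e-10)
  }

  # bootstrap-style duplicated columns create distance-0 ties: still defined
  tab <- random_table(n_taxa = 20, n_samples = 6, seed = 1)
  x <- unclass(tab)[, c(1, 1, 2, 4, 4, 5)]
  colnames(x) <- paste0("r", 1:6)
  D <- bray_curtis(count_table(x))
  r <- anosim_r(D, two_group_map(colnames(x)))
  expect_true(is.finite(r) && r >= -1 && r <= 1)
})

test_that("PERMANOVA partitions sums of squares per definition", {
  # univariate {0,0} vs {1,1}: SS_T = 1, SS_W = 0 -> R2 = 1, F infinite
  D <- labelled_dist(c(0, 0, 1, 1))
  g <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  fit <- permanova(D, g)
  expect_equal(fit$SS_T, 1)
  expect_equal(fit$SS_W, 0)
  expect_equal(fit$R2, 1)
  expect_true(is.infinite(fit$pseudo_F))

  # algebraic identity SS_A + SS_W = SS_T and R2 in [0, 1] on random data
  for (seed in 1:5) {
    tab <- random_table(n_taxa = 25, n_samples = 9, seed = seed)
    gm <- two_group_map(colnames(tab))
    fit <- permanova(bray_curtis(tab), gm)
    expect_equal(fit$SS_A + fit$SS_W, fit$SS_T, tolerance = 1e-12)
    expect_true(fit$R2 >= 0 && fit$R2 <= 1)
  }

  expect_error(permanova(labelled_dist(c(1, 1, 1, 1)), g), "identical")
})

test_that("PERMANOVA pseudo-F equals classic one-way ANOVA F on univariate data", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:4, 1)
    n_per <- sample(3:6, 1)
    y <- rnorm(k * n_per, mean = rep(seq_len(k), each = n_per))
    grp <- rep(LETTERS[seq_len(k)], each = n_per)
    ids <- paste0("s", seq_along(y))
    fit <- permanova(labelled_dist(y, ids), setNames(grp, ids))
    f_classic <- anova(lm(y ~ grp))$`F value`[1]
    expect_equal(fit$pseudo_F, f_classic, tolerance = 1e-8)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  for (seed in 1:5) {
    tab <- random_table(n_taxa = 30, n_samples = 10, seed = seed)
    gm <- two_group_map(colnames(tab))
    D <- bray_curtis(tab)
    fit <- permanova(D, gm)
    ref <- vegan::adonis2(D ~ group, data = as.data.frame(gm), permutations = 2)
    expect_equal(fit$R2, ref$R2[1], tolerance = 1e-10)
    expect_equal(fit$pseudo_F, ref$F[1], tolerance = 1e-10)
  }
})

test_that("exact permutation moments: mean R = 0, mean R2 = (a-1)/(N-1)", {
  for (case in list(c(3, 3), c(4, 4), c(3, 5))) {
    tab <- random_table(n_taxa = 20, n_samples = sum(case), seed = sum(case))
    D <- bray_curtis(tab)
    ids <- colnames(tab)
    splits <- all_label_splits(case[1], case[2])
    rs <- vapply(splits, function(g) anosim_r(D, setNames(g, ids)), numeric(1))
    r2s <- vapply(splits, function(g) permanova(D, setNames(g, ids))$R2, numeric(1))
    expect_equal(mean(rs), 0, tolerance = 1e-12)
    expect_equal(mean(r2s), (2 - 1) / (sum(case) - 1), tolerance = 1e-12)
  }
})

test_that("statistics are invariant under simultaneous sample reordering", {
  tab <- random_table(n_taxa = 25, n_samples = 8, seed = 4)
  gm <- two_group_map(colnames(tab))
  D <- bray_curtis(tab)
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  Dp <- as.dist(as.matrix(D)[perm, perm])
  expect_equal(anosim_r(Dp, gm), anosim_r(D, gm), tolerance = 1e-12)
  expect_equal(permanova(Dp, gm)$R2, permanova(D, gm)$R2, tolerance = 1e-12)
})

test_that("permutation test p-values match exhaustive enumeration", {
  # perfectly separated 3+3 design: only the two identity-equivalent splits
  # reach R = 1, so the exhaustive p is 2/20 = 1/10
  x <- matrix(c(10, 0, 11, 0, 12, 0, 0, 10, 0, 11, 0, 12), nrow = 2,
              dimnames = list(c("t1", "t2"), paste0("s", 1:6)))
  tab <- count_table(x)
  gm <- two_group_map(colnames(tab))
  D <- bray_curtis(tab)
  obs <- anosim_r(D, gm)
  splits <- all_label_splits(3, 3)
  rs <- vapply(splits, function(g) anosim_r(D, setNames(g, colnames(tab))),
               numeric(1))
  expect_equal(mean(rs >= obs - 1e-12), 1 / 10)

  # Monte-Carlo p within 3 binomial SEs of the exhaustive p
  fit <- permutation_test(D, gm, "ANOSIM", n_permutations = 10000, seed = 5)
  p_exh <- mean(rs >= obs - 1e-12)
  se <- sqrt(p_exh * (1 - p_exh) / 10000)
  expect_lt(abs(fit$p_value - p_exh), 3 * se + 1e-4)
  expect_equal(fit$statistic, obs)
})

test_that("permutation test is seed-deterministic with a seed-free statistic", {
  tab <- random_table(n_taxa = 20, n_samples = 8, seed = 2)
  gm <- two_group_map(colnames(tab))
  D <- bray_curtis(tab)
  a <- permutation_test(D, gm, "ANOSIM", n_permutations = 99, seed = 1)
  b <- permutation_test(D, gm, "ANOSIM", n_permutations = 99, seed = 1)
  c <- permutation_test(D, gm, "ANOSIM", n_permutations = 99, seed = 2)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$statistic, c$statistic)  # statistic ignores the seed
  expect_gt(a$p_value, 0)                 # +1 correction forbids p = 0

  # n_permutations = 1 can only give 1/2 or 1
  p1 <- permutation_test(D, gm, "ANOSIM", n_permutations = 1, seed = 3)$p_value
  expect_true(p1 %in% c(0.5, 1))

  pv <- permutation_test(D, gm, "PERMANOVA", n_permutations = 99, seed = 1)
  expect_equal(pv$R2, permanova(D, gm)$R2)
  td <- tidy(pv)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$test, "PERMANOVA")
  expect_equal(td$n_permutations, 99)
})

test_that("group validation rejects undersized or missing groups", {
  tab <- random_table(n_taxa = 10, n_samples = 5, seed = 1)
  D <- bray_curtis(tab)
  expect_error(anosim_r(D, setNames(c("A", "A", "A", "A", "B"), colnames(tab))),
               "fewer than two")
  expect_error(anosim_r(D, setNames(rep("A", 5), colnames(tab))),
               "at least two groups")
  expect_error(anosim_r(D, setNames(rep(c("A", "B"), 2), colnames(tab)[1:4])),
               "missing from groups")
})
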