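# Small fixtures built in code, shared across test files.

toy_table <- function() {
  count_table(matrix(
    c(5L, 0L, 3L, 2L,
      1L, 4L, 0L, 6L,
      0L, 2L, 7L, 1L),
    nrow = 4,
    dimnames = list(paste0("t", 1:4), paste0("s", 1:3))
  ))
}

random_table <- function(n_taxa = 30, n_samples = 8, depth = 500, seed = 1) {
  set.seed(seed)
  p <- rlnorm(n_taxa, 0, 1.5)
  x <- rmultinom(n_samples, depth, p / sum(p))
  dimnames(x) <- list(sprintf("t%02d", seq_len(n_taxa)),
                      sprintf("s%02d", seq_len(n_samples)))
  count_table(x)
}

two_group_map <- function(sample_ids) {
  n <- length(sample_ids)
  tibble::tibble(sample_id = sample_ids,
                 group = rep(c("A", "B"), each = ceiling(n / 2))[seq_len(n)])
}

# dist object from an explicit lower-triangle vector (column-major order)
dist_from_lower <- function(values, labels) {
  structure(values, Size = length(labels), Labels = labels,
            Diag = FALSE, Upper = FALSE, class = "dist")
}

# Euclidean dist over univariate points, labelled
labelled_dist <- function(y, labels = paste0("s", seq_along(y))) {
  d <- dist(y)
  attr(d, "Labels") <- labels
  d
}

# All distinct two-group label assignments of n1 + n2 samples (oracle for
# exhaustive permutation enumeration).
all_label_splits <- function(n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  lapply(seq_len(ncol(combos)), function(k) {
    g <- rep("B", n)
    g[combos[, k]] <- "A"
    g
  })
}
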