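#' Bray-Curtis dissimilarity between samples
#'
#' For samples i and j with taxon vectors x_i, x_j,
#' `d_ij = sum_k |x_ki - x_kj| / sum_k (x_ki + x_kj)`.
#' Abundance-weighted: dominated by the most abundant taxa.  Works on raw,
#' rarefied, or CSS-normalized tables — the caller owns that pairing.
#'
#' @param table A taxa-by-samples matrix ([count_table()] or the output of
#'   [css_normalize()]).
#' @return A [stats::dist] object over the samples, values in \[0, 1\].
#' @examples
#' tab <- count_table(matrix(c(1L, 2L, 3L, 3L, 2L, 1L), nrow = 3,
#'                           dimnames = list(letters[1:3], c("s1", "s2"))))
#' bray_curtis(tab)  # (2 + 0 + 2) / 12 = 1/3
#' @export
bray_curtis <- function(table) {
  x <- as_value_matrix(table)
  totals <- colSums(x)
  if (any(totals <= 0)) {
    abort(paste0("sample with zero total (Bray-Curtis undefined): ",
                 paste(colnames(x)[totals <= 0], collapse = ", ")))
  }
  d <- .bray_curtis_lower(x)
  make_dist(d, colnames(x), "bray-curtis")
}

#' Binary Jaccard dissimilarity between samples
#'
#' With A, B the sets of taxa present (count > 0) in two samples,
#' `d = 1 - |A intersect B| / |A union B|`.  Presence/absence only, so rare
#' and abundant taxa carry equal weight; identical before and after CSS
#' normalization because CSS preserves the zero pattern.
#'
#' @inheritParams bray_curtis
#' @return A [stats::dist] object over the samples, values in \[0, 1\].
#' @export
jaccard_binary <- function(table) {
  x <- as_value_matrix(table)
  present <- colSums(x > 0)
  if (any(present == 0)) {
    abort(paste0("sample with empty presence set: ",
                 paste(colnames(x)[present == 0], collapse = ", ")))
  }
  d <- .jaccard_binary_lower(x)
  make_dist(d, colnames(x), "jaccard")
}

#' Compute a dissimilarity matrix by metric name
#'
#' @inheritParams bray_curtis
#' @param metric `"bray-curtis"` or `"jaccard"`.
#' @return A [stats::dist] object.
#' @export
dissimilarity <- function(table, metric = c("bray-curtis", "jaccard")) {
  metric <- match.arg(metric)
  switch(metric,
         "bray-curtis" = bray_curtis(table),
         "jaccard" = jaccard_binary(table))
}

as_value_matrix <- function(table) {
  x <- unclass(table)
  if (!is.matrix(x)) abort("expected a taxa-by-samples matrix")
  storage.mode(x) <- "double"
  if (ncol(x) < 2) abort("need at least two samples for a dissimilarity matrix")
  x
}

make_dist <- function(values, labels, method) {
  structure(values,
            Size = length(labels),
            Labels = labels,
            Diag = FALSE,
            Upper = FALSE,
            method = method,
            class = "dist")
}
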