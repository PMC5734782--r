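#' Cumulative-sum-scaling factors
#'
#' For each sample the scaling factor is the cumulative sum of that sample's
#' counts up to (and including) the `quantile_p` quantile of its *positive*
#' counts.  Quantiles use the linear-interpolation order-statistic convention
#' (R type 7), one fixed definition so results are bit-reproducible.
#'
#' @param table A [count_table()].
#' @param quantile_p Quantile of the positive-count distribution, in (0, 1].
#'   `quantile_p = 1` recovers per-sample totals (total-sum scaling).
#'
#' @return Named numeric vector of strictly positive per-sample factors.
#' @examples
#' tab <- count_table(matrix(c(1L, 2L, 3L, 100L), ncol = 1,
#'                           dimnames = list(letters[1:4], "s1")))
#' css_scaling_factors(tab, quantile_p = 0.5)  # median 2.5 -> 1 + 2 = 3
#' @export
css_scaling_factors <- function(table, quantile_p = 0.5) {
  if (quantile_p <= 0 || quantile_p > 1) abort("quantile_p must be in (0, 1]")
  x <- unclass(table)
  s <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    pos <- col[col > 0]
    if (length(pos) == 0) {
      abort(paste0("sample '", colnames(x)[j], "' has no positive counts"))
    }
    q <- interp_quantile(pos, quantile_p)
    sum(col[col <= q])
  }, numeric(1))
  setNames(s, colnames(x))
}

#' Cumulative-sum-scaling normalization
#'
#' Divides each count by its sample's CSS scaling factor and multiplies by a
#' common scale constant.  Zero counts map to zero values, so presence/absence
#' structure (and hence any binary dissimilarity) is unchanged by CSS.
#'
#' @inheritParams css_scaling_factors
#' @param scale_constant Common multiplier for the scaled values (default
#'   1000, the conventional CSS export scale; only relative abundances matter
#'   to the dissimilarities used downstream).
#'
#' @return A numeric matrix of class `normalized_table` with attributes
#'   `scaling_factors`, `quantile_p` and `scale_constant`.
#' @export
css_normalize <- function(table, quantile_p = 0.5, scale_constant = 1000) {
  if (scale_constant <= 0) abort("scale_constant must be positive")
  s <- css_scaling_factors(table, quantile_p)
  x <- unclass(table)
  values <- sweep(x, 2, s, "/") * scale_constant
  structure(values,
            scaling_factors = s,
            quantile_p = quantile_p,
            scale_constant = scale_constant,
            class = c("normalized_table", class(matrix())))
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("<normalized_table> %d taxa x %d samples (CSS, quantile %.2f, scale %g)\n",
              nrow(x), ncol(x), attr(x, "quantile_p"), attr(x, "scale_constant")))
  invisible(x)
}

#' Rarefy a count table to a fixed sequencing depth
#'
#' Each sample with at least `depth` reads is replaced by a random subsample
#' of exactly `depth` reads drawn without replacement (a multivariate
#' hypergeometric draw).  Samples shallower than `depth` are dropped with a
#' warning rather than resampled with replacement — the standard rarefaction
#' contract.
#'
#' @param table A [count_table()].
#' @param depth Target reads per sample (>= 1).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#'
#' @return A `count_table` whose retained columns each sum to exactly
#'   `depth`, with a `"dropped_samples"` attribute listing any discarded
#'   sample identifiers.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth < 1) abort("depth must be >= 1")
  validate_count_table(table)
  x <- unclass(table)
  storage.mode(x) <- "integer"
  totals <- colSums(x)
  keep <- totals >= depth
  if (!any(keep)) {
    abort(paste0("all samples are shallower than depth ", depth))
  }
  dropped <- colnames(x)[!keep]
  if (length(dropped) > 0) {
    warn(paste0(length(dropped), " sample(s) shallower than depth ", depth,
                " dropped: ", paste(head(dropped, 5), collapse = ", ")))
  }
  xk <- x[, keep, drop = FALSE]
  at_depth <- colSums(xk) == depth
  out <- xk
  if (any(!at_depth)) {
    sub <- with_seed(seed, .rarefy_matrix(xk[, !at_depth, drop = FALSE],
                                          as.integer(depth)))
    out[, !at_depth] <- sub
  }
  res <- count_table(out)
  attr(res, "dropped_samples") <- dropped
  res
}
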