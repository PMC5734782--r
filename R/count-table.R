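#' Construct a count table
#'
#' A count table is the universal currency of the pipeline: an integer matrix
#' of read counts with taxa as rows and samples as columns, both carrying
#' unique identifiers.  This mirrors the classic OTU-table convention of
#' amplicon workflows.
#'
#' @param counts A matrix of non-negative integers with unique rownames
#'   (taxon identifiers) and unique colnames (sample identifiers).
#'
#' @return An integer matrix of class `count_table`.
#' @examples
#' tab <- count_table(matrix(c(1L, 3L, 2L, 4L), nrow = 2,
#'                           dimnames = list(c("t1", "t2"), c("s1", "s2"))))
#' sample_totals(tab)
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  validate_count_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(matrix()))
  counts
}

validate_count_table <- function(counts) {
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    abort("count table needs at least one taxon and one sample")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    abort(paste0("duplicate taxon identifier: '", dup, "'"))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    abort(paste0("duplicate sample identifier: '", dup, "'"))
  }
  if (!is.numeric(counts)) abort("counts must be numeric")
  if (anyNA(counts)) abort("counts contain missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "counts must be non-negative integers; offending cell taxon '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])
    ))
  }
  invisible(counts)
}

#' Per-sample read totals
#'
#' @param table A count table (or any taxa-by-samples numeric matrix).
#' @return Named numeric vector of column sums.
#' @export
sample_totals <- function(table) {
  colSums(unclass(table))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa x %d samples, total reads %s\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  nr <- min(nrow(x), 6L); nc <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE])
  if (nrow(x) > nr || ncol(x) > nc) {
    cat(sprintf("... %d more taxa, %d more samples\n",
                nrow(x) - nr, ncol(x) - nc))
  }
  invisible(x)
}

#' Collapse a count table to a coarser taxonomic resolution
#'
#' Rows sharing a cluster label at the requested hierarchy level are summed,
#' emulating re-clustering of OTUs at a lower similarity cutoff (e.g. moving
#' from 99% to 90% similarity).  Per-sample totals are conserved exactly.
#'
#' @param table A [count_table()].
#' @param hierarchy A taxonomy hierarchy as built by [make_hierarchy()] or
#'   read by [read_taxonomy_hierarchy()]: a data frame with a `taxon_id`
#'   column and one column of cluster labels per resolution level.
#' @param level A resolution label; must be one of the hierarchy's levels.
#'
#' @return A `count_table` whose taxon identifiers are the cluster labels at
#'   `level`.
#' @examples
#' tab <- count_table(matrix(c(1L, 2L, 3L), ncol = 1,
#'                           dimnames = list(c("a", "b", "c"), "s1")))
#' hier <- tibble::tibble(taxon_id = c("a", "b", "c"),
#'                        `99` = c("a", "b", "c"),
#'                        `97` = c("u", "u", "v"))
#' attr(hier, "levels") <- c("99", "97")
#' collapse_resolution(tab, hier, "97")
#' @export
collapse_resolution <- function(table, hierarchy, level) {
  validate_count_table(table)
  levels <- hierarchy_levels(hierarchy)
  if (!level %in% levels) {
    abort(paste0("unknown resolution level '", level, "'; hierarchy has: ",
                 paste(levels, collapse = ", ")))
  }
  map <- setNames(as.character(hierarchy[[level]]), hierarchy$taxon_id)
  missing <- setdiff(rownames(table), names(map))
  if (length(missing) > 0) {
    abort(paste0("taxa missing from hierarchy at level '", level, "': ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  labels <- map[rownames(table)]
  collapsed <- rowsum(unclass(table), group = labels, reorder = TRUE)
  count_table(collapsed)
}

hierarchy_levels <- function(hierarchy) {
  lv <- attr(hierarchy, "levels")
  if (is.null(lv)) lv <- setdiff(names(hierarchy), "taxon_id")
  lv
}

# Refinement consistency: taxa merged at a finer level must stay merged at
# every coarser level.  Violations would corrupt the resolution axis, so they
# are hard errors at load/build time.
validate_hierarchy <- function(hierarchy) {
  if (!"taxon_id" %in% names(hierarchy)) {
    abort("hierarchy needs a 'taxon_id' column")
  }
  levels <- hierarchy_levels(hierarchy)
  if (length(levels) < 1) abort("hierarchy needs at least one level")
  for (lv in levels) {
    if (anyNA(hierarchy[[lv]])) {
      abort(paste0("hierarchy level '", lv, "' has missing labels"))
    }
  }
  if (length(levels) >= 2) {
    for (k in seq_len(length(levels) - 1)) {
      fine <- as.character(hierarchy[[levels[k]]])
      coarse <- as.character(hierarchy[[levels[k + 1]]])
      # each fine cluster must map to exactly one coarse cluster
      n_images <- tapply(coarse, fine, function(z) length(unique(z)))
      if (any(n_images > 1)) {
        bad <- names(n_images)[n_images > 1][1]
        abort(sprintf(
          "hierarchy is not refinement-consistent: cluster '%s' at level '%s' splits at coarser level '%s'",
          bad, levels[k], levels[k + 1]
        ))
      }
    }
  }
  invisible(hierarchy)
}
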