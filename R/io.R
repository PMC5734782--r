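#' Read a count table from a classic OTU TSV (or BIOM v1) file
#'
#' The classic dialect is a tab-separated file whose first column holds taxon
#' identifiers and whose header row holds sample identifiers.  Tables stored
#' with samples as rows are accepted via `orientation = "samples_rows"` and
#' transposed into the canonical taxa-rows form.  BIOM v1 (JSON) files are
#' read through the biomformat package behind the same contract.
#'
#' @param path Path to the file.
#' @param orientation `"taxa_rows"` (default, classic OTU convention) or
#'   `"samples_rows"`.
#' @param format `"tsv"` (default) or `"biom"` for BIOM v1 JSON.
#'
#' @return A [count_table()].
#' @export
read_count_table <- function(path,
                             orientation = c("taxa_rows", "samples_rows"),
                             format = c("tsv", "biom")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa rows x sample columns
    return(count_table(m))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) abort("count table file needs an id column plus >= 1 data column")
  ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-integer or negative count at row '%s', column '%s' (value '%s')",
      ids[bad[1, 1]], colnames(body)[bad[1, 2]], body[bad[1, , drop = FALSE]]
    ))
  }
  if (orientation == "samples_rows") num <- t(num)
  count_table(num)
}

#' Write a count table as a classic OTU TSV
#'
#' Inverse of [read_count_table()]: re-reading the written file reproduces
#' the table exactly.
#'
#' @param table A [count_table()].
#' @param path Destination path.
#' @param id_column Header for the taxon-identifier column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_column = "taxon_id") {
  validate_count_table(table)
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) abort(paste0("could not write '", path, "': ",
                                conditionMessage(ok)))
  invisible(path)
}

#' Read a sample-to-group mapping
#'
#' Two-column tab-separated file: sample identifier, group label.  Repeated
#' rows with the same assignment are collapsed; the same sample mapped to two
#' different groups is an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) abort("group map needs two columns: sample_id, group")
  gm <- tibble::tibble(sample_id = df[[1]], group = df[[2]])
  gm <- dplyr::distinct(gm)
  conflicts <- gm$sample_id[duplicated(gm$sample_id)]
  if (length(conflicts) > 0) {
    abort(paste0("sample mapped to conflicting groups: ",
                 paste(unique(conflicts), collapse = ", ")))
  }
  if (any(!nzchar(gm$sample_id))) abort("empty sample identifier in group map")
  gm
}

#' Coerce assignments to a canonical group map
#'
#' Accepts a two-column data frame (`sample_id`, `group`) or a named
#' character vector (names = sample ids).
#'
#' @param groups Group assignments.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      gm <- tibble::tibble(sample_id = as.character(groups[[1]]),
                           group = as.character(groups[[2]]))
    } else {
      gm <- tibble::tibble(sample_id = as.character(groups$sample_id),
                           group = as.character(groups$group))
    }
  } else if (!is.null(names(groups))) {
    gm <- tibble::tibble(sample_id = names(groups),
                         group = as.character(groups))
  } else {
    abort("groups must be a data frame or a named vector")
  }
  if (anyDuplicated(gm$sample_id)) {
    gm <- dplyr::distinct(gm)
    if (anyDuplicated(gm$sample_id)) abort("conflicting group assignments")
  }
  gm
}

#' Read a taxonomy hierarchy table
#'
#' Tab-separated file with a `taxon_id` column and one column of cluster
#' labels per resolution level, ordered finest to coarsest.  Refinement
#' consistency (taxa merged at a finer level stay merged at all coarser
#' levels) is validated on load and violations are hard errors.
#'
#' @param path Path to the TSV file.
#' @param levels Optional character vector giving the level order (finest
#'   first); defaults to the file's column order.
#' @return A tibble with a `"levels"` attribute.
#' @export
read_taxonomy_hierarchy <- function(path, levels = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (!"taxon_id" %in% names(df)) names(df)[1] <- "taxon_id"
  hier <- tibble::as_tibble(df)
  attr(hier, "levels") <- levels %||% setdiff(names(hier), "taxon_id")
  validate_hierarchy(hier)
  hier
}

#' Write a taxonomy hierarchy table
#'
#' @param hierarchy A hierarchy tibble (see [make_hierarchy()]).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_hierarchy <- function(hierarchy, path) {
  write.table(as.data.frame(hierarchy), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a sample-to-group mapping
#'
#' @param groups A group map (see [as_group_map()]).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(groups, path) {
  gm <- as_group_map(groups)
  write.table(as.data.frame(gm), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
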