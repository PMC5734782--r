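#' Sweep configuration
#'
#' Bundles every tunable of the bootstrap confidence-interval sweep.  The
#' defaults mirror the study design the package emulates: 1000 bootstrap
#' subsamples per cell, 95% percentile intervals, cumulative-sum-scaling for
#' effort-only sweeps, and raw rarefied counts (no re-normalization) for
#' depth sweeps.
#'
#' @param effort_grid Integer vector of per-group sample sizes (each >= 2).
#'   Groups are resampled *with replacement*, so efforts may exceed the
#'   number of available samples.
#' @param depth_grid Rarefaction depths, or `NA` for "no rarefaction".  Mixed
#'   grids are allowed.
#' @param resolution_levels Hierarchy levels to collapse to, or `NA` for the
#'   table's native resolution.
#' @param metric Dissimilarity metrics to sweep: `"bray-curtis"` and/or
#'   `"jaccard"`.
#' @param test Effect-size statistics to sweep: `"ANOSIM"` (R) and/or
#'   `"PERMANOVA"` (R2).
#' @param n_boot Bootstrap replicates per cell (default 1000).
#' @param ci_level Confidence level for the percentile interval (default 0.95).
#' @param normalization `"css"` (default) or `"none"`; applied when a cell is
#'   not rarefied.
#' @param renormalize_after_rarefy Re-apply CSS after rarefaction?  Default
#'   `FALSE`: depth sweeps run on raw rarefied counts.
#' @param css_quantile,css_scale CSS parameters (see [css_normalize()]).
#' @param seed Master integer seed; every cell and replicate derives its own
#'   stream from it, so sweeps are bit-reproducible.
#'
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(effort_grid,
                         depth_grid = NA,
                         resolution_levels = NA,
                         metric = "bray-curtis",
                         test = "ANOSIM",
                         n_boot = 1000,
                         ci_level = 0.95,
                         normalization = c("css", "none"),
                         renormalize_after_rarefy = FALSE,
                         css_quantile = 0.5,
                         css_scale = 1000,
                         seed = 1L) {
  normalization <- match.arg(normalization)
  metric <- match.arg(metric, c("bray-curtis", "jaccard"), several.ok = TRUE)
  test <- match.arg(test, c("ANOSIM", "PERMANOVA"), several.ok = TRUE)
  if (n_boot < 2) abort("n_boot must be >= 2")
  if (any(effort_grid < 2)) abort("effort sizes must be >= 2")
  if (any(!is.na(depth_grid) & depth_grid < 1)) abort("depths must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) abort("ci_level must be in (0, 1)")
  structure(
    list(effort_grid = as.integer(effort_grid), depth_grid = depth_grid,
         resolution_levels = resolution_levels, metric = metric, test = test,
         n_boot = as.integer(n_boot), ci_level = ci_level,
         normalization = normalization,
         renormalize_after_rarefy = renormalize_after_rarefy,
         css_quantile = css_quantile, css_scale = css_scale,
         seed = as.integer(seed)),
    class = "sweep_config"
  )
}

#' Bootstrap replicate effect sizes for one sweep cell
#'
#' Runs the per-replicate pipeline of the sweep: (1) collapse the table to
#' the requested taxonomic resolution; (2) rarefy every sample to `depth`
#' with a replicate-specific derived seed, dropping samples shallower than
#' the depth; (3) optionally CSS-normalize; (4) draw `effort` samples per
#' group uniformly *with replacement*, keeping duplicates as distinct
#' sampling units; (5) compute the dissimilarity matrix and the effect-size
#' statistic (ANOSIM R or PERMANOVA R2).
#'
#' @param table A [count_table()].
#' @param groups Group assignments (see [as_group_map()]).
#' @param config A [sweep_config()]; supplies metric/test defaults, CSS
#'   settings, and the master seed.
#' @param effort Samples drawn per group (with replacement).
#' @param depth Rarefaction depth, or `NA` for none.
#' @param resolution Hierarchy level, or `NA` for native resolution.
#' @param hierarchy Taxonomy hierarchy; required when `resolution` is set.
#' @param metric,test Override the (first) metric/test in `config`.
#' @param seed Override the stream seed (used by [run_sweep()] to give each
#'   cell its own stream).
#'
#' @return Numeric vector of `config$n_boot` replicate statistics.
#' @export
bootstrap_replicates <- function(table, groups, config, effort,
                                 depth = NA, resolution = NA,
                                 hierarchy = NULL,
                                 metric = config$metric[1],
                                 test = config$test[1],
                                 seed = config$seed) {
  gm <- as_group_map(groups)
  if (effort < 2) abort("effort must be >= 2")

  # (1) resolution is a property of the table: collapse once, outside the loop
  if (!is.na(resolution)) {
    if (is.null(hierarchy)) abort("resolution requested but no hierarchy given")
    table <- collapse_resolution(table, hierarchy, resolution)
  }
  x <- unclass(table)
  storage.mode(x) <- "integer"
  gm <- gm[gm$sample_id %in% colnames(x), , drop = FALSE]

  rarefied_cell <- !is.na(depth)
  use_css <- (config$normalization == "css") &&
    (!rarefied_cell || isTRUE(config$renormalize_after_rarefy))

  if (rarefied_cell) {
    deep_enough <- colSums(x) >= depth
    lost <- tapply(!deep_enough[gm$sample_id], gm$group, all)
    if (any(lost)) {
      abort(paste0("group '", names(lost)[lost][1],
                   "' has no sample with >= ", depth, " reads"))
    }
    gm <- gm[deep_enough[gm$sample_id], , drop = FALSE]
    x <- x[, gm$sample_id, drop = FALSE]
  } else if (use_css) {
    # no per-replicate randomness before the bootstrap draw: normalize once
    x <- unclass(css_normalize(count_table(x), config$css_quantile,
                               config$css_scale))
  }

  group_of <- split(seq_len(ncol(x)), gm$group[match(colnames(x), gm$sample_id)])
  if (length(group_of) < 2) abort("need at least two groups")
  stat_of <- replicate_stat_fun(metric, test, effort, names(group_of))

  vapply(seq_len(config$n_boot), function(b) {
    xb <- x
    if (rarefied_cell) {
      xb <- with_seed(mix_seed(seed, b, 1L),
                      .rarefy_matrix(xb, as.integer(depth)))
      if (use_css) {
        xb <- unclass(css_normalize(count_table(xb), config$css_quantile,
                                    config$css_scale))
      }
    }
    cols <- with_seed(mix_seed(seed, b, 2L), {
      unlist(lapply(group_of, function(idx) {
        idx[sample.int(length(idx), effort, replace = TRUE)]
      }), use.names = FALSE)
    })
    stat_of(xb[, cols, drop = FALSE])
  }, numeric(1))
}

# Build a fast statistic evaluator for resampled matrices with a fixed
# group layout (effort columns per group, in group order).
replicate_stat_fun <- function(metric, test, effort, group_names) {
  a <- length(group_names)
  N <- a * effort
  g <- rep(group_names, each = effort)
  jj <- rep.int(seq_len(N - 1), times = (N - 1):1)
  ii <- sequence((N - 1):1, from = 2:N)
  n_per_group <- setNames(rep(effort, a), group_names)
  dist_fun <- if (metric == "bray-curtis") .bray_curtis_lower else .jaccard_binary_lower
  function(xb) {
    storage.mode(xb) <- "double"
    d <- dist_fun(xb)
    if (test == "ANOSIM") {
      anosim_r_from_ranks(rank(d), g, ii, jj)
    } else {
      permanova_from_d2(d^2, g, ii, jj, n_per_group)$R2
    }
  }
}

#' Percentile confidence interval of bootstrap replicates
#'
#' Lower and upper bounds are the `(1 - ci_level)/2` and `1 - (1 - ci_level)/2`
#' linear-interpolation percentiles of the replicate values; the point
#' estimate is their arithmetic mean.
#'
#' @param values Numeric vector of replicate statistics (length >= 2).
#' @param ci_level Confidence level (default 0.95).
#' @return Named list with `lower`, `mean`, `upper`.
#' @examples
#' percentile_ci(0:100)  # lower 2.5, mean 50, upper 97.5
#' @export
percentile_ci <- function(values, ci_level = 0.95) {
  if (length(values) < 2) abort("need at least 2 values for a percentile CI")
  alpha <- (1 - ci_level) / 2
  list(lower = interp_quantile(values, alpha),
       mean = mean(values),
       upper = interp_quantile(values, 1 - alpha))
}

#' Run a full confidence-interval sweep
#'
#' Computes bootstrap effect-size confidence intervals over the full grid of
#' sampling effort x rarefaction depth x taxonomic resolution x metric x
#' test.  Each cell gets `n_boot` replicates via [bootstrap_replicates()] and
#' is summarized by [percentile_ci()].  Cells that fail (e.g. a depth no
#' sample reaches) are recorded with their reason, not dropped.
#'
#' @inheritParams bootstrap_replicates
#' @param hierarchy Taxonomy hierarchy, or `NULL` when no resolution levels
#'   are swept.
#' @param progress Print one line per completed cell?
#'
#' @return A tibble of class `ci_sweep` with one row per cell: `test`,
#'   `metric`, `resolution`, `depth`, `effort`, `n_boot`, `mean`, `lower`,
#'   `upper`, `width`, `status`.
#' @export
run_sweep <- function(table, groups, config, hierarchy = NULL,
                      progress = FALSE) {
  grid <- tidyr::expand_grid(
    test = config$test,
    metric = config$metric,
    resolution = config$resolution_levels,
    depth = config$depth_grid,
    effort = config$effort_grid
  )
  rows <- purrr::pmap(c(grid, list(.cell = seq_len(nrow(grid)))),
    function(test, metric, resolution, depth, effort, .cell) {
      res <- tryCatch({
        values <- bootstrap_replicates(
          table, groups, config, effort = effort, depth = depth,
          resolution = resolution, hierarchy = hierarchy,
          metric = metric, test = test,
          seed = mix_seed(config$seed, .cell)
        )
        ci <- percentile_ci(values, config$ci_level)
        tibble::tibble(mean = ci$mean, lower = ci$lower, upper = ci$upper,
                       width = ci$upper - ci$lower, status = "ok")
      }, error = function(e) {
        tibble::tibble(mean = NA_real_, lower = NA_real_, upper = NA_real_,
                       width = NA_real_,
                       status = paste0("failed: ", conditionMessage(e)))
      })
      if (progress) {
        message(sprintf("cell %d/%d: %s/%s effort=%d depth=%s res=%s [%s]",
                        .cell, nrow(grid), test, metric, effort,
                        as.character(depth), as.character(resolution),
                        res$status))
      }
      res
    })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  out$n_boot <- config$n_boot
  out <- dplyr::relocate(out, "n_boot", .before = "mean")
  class(out) <- c("ci_sweep", class(out))
  attr(out, "ci_level") <- config$ci_level
  out
}

#' Average fractional CI-width decrease between two depths
#'
#' For every combination of the remaining factor levels present at both
#' depths, computes `(width_from - width_to) / width_from` and averages,
#' returning a percentage.  Cells with zero `width_from` are excluded with a
#' warning.
#'
#' @param records A `ci_sweep` tibble from [run_sweep()].
#' @param from_depth,to_depth The two depths to contrast (typically the
#'   shallowest and deepest of the grid).
#' @return Mean percentage decrease in CI width (positive = narrower at
#'   `to_depth`).
#' @export
ci_width_decrease <- function(records, from_depth, to_depth) {
  keys <- c("test", "metric", "resolution", "effort")
  a <- dplyr::filter(records, .data$depth == from_depth, .data$status == "ok")
  b <- dplyr::filter(records, .data$depth == to_depth, .data$status == "ok")
  m <- dplyr::inner_join(
    dplyr::select(a, dplyr::all_of(keys), width_from = "width"),
    dplyr::select(b, dplyr::all_of(keys), width_to = "width"),
    by = keys
  )
  if (nrow(m) == 0) abort("no matched cells at the two depths")
  zero <- m$width_from <= 0
  if (any(zero)) {
    warn(paste0(sum(zero), " cell(s) with zero width at from_depth excluded"))
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) == 0) abort("no cells with positive width at from_depth")
  mean((m$width_from - m$width_to) / m$width_from) * 100
}
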