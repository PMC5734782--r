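test_that("percentile CIs use linear-interpolation order statistics", {
  ci <- percentile_ci(0:100, 0.95)
  expect_equal(ci$lower, 2.5)
  expect_equal(ci$mean, 50)
  expect_equal(ci$upper, 97.5)

  ci2 <- percentile_ci(rep(0.3, 10))
  expect_equal(unlist(ci2), c(lower = 0.3, mean = 0.3, upper = 0.3))

  # two points interpolate linearly
  ci3 <- percentile_ci(c(0, 1), 0.95)
  expect_equal(ci3$lower, 0.025)
  expect_equal(ci3$upper, 0.975)

  expect_error(percentile_ci(1), "at least 2")
})

test_that("bootstrap replicates are reproducible and respect the pipeline", {
  ds <- simulate_grouped_dataset(synthetic_spec(
    n_taxa = 60, n_samples_per_group = c(a = 6, b = 6), depth = 500,
    effect_mode = "specialist", effect_strength = 1, seed = 3))
  cfg <- sweep_config(effort_grid = 5, n_boot = 3, seed = 9)
  v1 <- bootstrap_replicates(ds$table, ds$groups, cfg, effort = 5)
  v2 <- bootstrap_replicates(ds$table, ds$groups, cfg, effort = 5)
  expect_length(v1, 3)
  expect_identical(v1, v2)
  expect_true(all(v1 >= -1 & v1 <= 1))

  v3 <- bootstrap_replicates(ds$table, ds$groups, cfg, effort = 5, seed = 10)
  expect_false(identical(v1, v3))
})

test_that("two groups of copies of distinct columns give constant R = 1", {
  base <- c(50L, 30L, 0L, 5L)
  other <- c(0L, 2L, 60L, 40L)
  x <- cbind(a1 = base, a2 = base, a3 = base,
             b1 = other, b2 = other, b3 = other)
  rownames(x) <- paste0("t", 1:4)
  gm <- tibble::tibble(sample_id = colnames(x),
                       group = rep(c("a", "b"), each = 3))
  cfg <- sweep_config(effort_grid = 4, n_boot = 10, normalization = "none",
                      seed = 1)
  v <- bootstrap_replicates(count_table(x), gm, cfg, effort = 4)
  expect_equal(v, rep(1, 10))
})

test_that("replicate means track the full-data statistic at full effort", {
  ds <- simulate_grouped_dataset(synthetic_preset("strong", seed = 2))
  full_r <- anosim_r(bray_curtis(css_normalize(ds$table)), ds$groups)
  cfg <- sweep_config(effort_grid = 19, n_boot = 60, seed = 4)
  v <- bootstrap_replicates(ds$table, ds$groups, cfg, effort = 19)
  expect_lt(abs(mean(v) - full_r), 0.1)
})

test_that("run_sweep covers the grid, records failures, and is deterministic", {
  ds <- simulate_grouped_dataset(synthetic_spec(
    n_taxa = 50, n_samples_per_group = c(a = 5, b = 5), depth = 300,
    effect_mode = "specialist", effect_strength = 1.2, seed = 5))
  cfg <- sweep_config(effort_grid = c(3, 5), depth_grid = c(100, 5000),
                      metric = "bray-curtis", test = "ANOSIM",
                      n_boot = 5, normalization = "none", seed = 7)
  sw <- run_sweep(ds$table, ds$groups, cfg)
  expect_equal(nrow(sw), 4)
  # no sample reaches depth 5000: those cells fail with a reason, others pass
  expect_true(all(grepl("failed", sw$status[sw$depth == 5000])))
  expect_true(all(sw$status[sw$depth == 100] == "ok"))
  ok <- dplyr::filter(sw, .data$status == "ok")
  expect_true(all(ok$lower <= ok$upper))
  expect_true(all(ok$width >= 0))

  sw2 <- run_sweep(ds$table, ds$groups, cfg)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))

  # resolution axis: coarser levels run through the same engine
  cfg3 <- sweep_config(effort_grid = 4, resolution_levels = c("99", "90"),
                       n_boot = 5, seed = 2)
  sw3 <- run_sweep(ds$table, ds$groups, cfg3, hierarchy = ds$hierarchy)
  expect_equal(nrow(sw3), 2)
  expect_true(all(sw3$status == "ok"))
})

test_that("CI width decrease averages matched cells as a percentage", {
  rec <- tibble::tibble(
    test = "ANOSIM", metric = "bray-curtis", resolution = NA,
    depth = rep(c(100, 20000), each = 2), effort = rep(c(5, 10), 2),
    n_boot = 10, mean = 0.5, lower = 0, upper = 1,
    width = c(0.4, 0.5, 0.2, 0.4), status = "ok"
  )
  # per-cell decreases 50% and 20% -> mean 35%
  expect_equal(ci_width_decrease(rec, 100, 20000), 35)

  rec$width[3:4] <- rec$width[1:2]  # equal widths -> 0%
  expect_equal(ci_width_decrease(rec, 100, 20000), 0)

  rec$width[1] <- 0  # zero-width origin cells are excluded with a warning
  expect_warning(out <- ci_width_decrease(rec, 100, 20000), "zero width")
  expect_equal(out, 0)
})

test_that("null-preset sweeps cover zero and strong-preset widths shrink with effort", {
  ds <- simulate_grouped_dataset(synthetic_preset("null", seed = 11))
  cfg <- sweep_config(effort_grid = c(5, 15), n_boot = 60, seed = 11)
  sw <- run_sweep(ds$table, ds$groups, cfg)
  expect_true(all(sw$lower <= 0 & sw$upper >= 0))

  ds2 <- simulate_grouped_dataset(synthetic_preset("strong", seed = 12))
  cfg2 <- sweep_config(effort_grid = c(5, 30), n_boot = 60, seed = 12)
  sw2 <- run_sweep(ds2$table, ds2$groups, cfg2)
  expect_lt(sw2$width[sw2$effort == 30], sw2$width[sw2$effort == 5])
})
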