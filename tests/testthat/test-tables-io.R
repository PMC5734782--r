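test_that("count table TSV round-trips exactly, both orientations", {
  tab <- count_table(matrix(c(1L, 3L, 2L, 4L), nrow = 2,
                            dimnames = list(c("t1", "t2"), c("s1", "s2"))))
  expect_equal(unname(sample_totals(tab)), c(4, 6))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_identical(unclass(back), unclass(tab))

  # samples-as-rows orientation transposes into canonical form
  path2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(tab), t(unclass(tab)), check.names = FALSE)
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_count_table(path2, orientation = "samples_rows")
  expect_identical(unclass(back2), unclass(tab))

  # a sample of all zeros survives the round trip
  tab0 <- count_table(matrix(c(1L, 2L, 0L, 0L), nrow = 2,
                             dimnames = list(c("t1", "t2"), c("s1", "s2"))))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab0, path3)
  expect_identical(unclass(read_count_table(path3)), unclass(tab0))

  r <- random_table(seed = 42)
  path4 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(r, path4)
  expect_identical(unclass(read_count_table(path4)), unclass(r))
})

test_that("malformed count tables are rejected with the offending cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "t1\t1\t2", "t2\t-1\t4"), path)
  expect_error(read_count_table(path), "t2")

  writeLines(c("taxon_id\ts1", "t1\t1.5"), path)
  expect_error(read_count_table(path), "non-integer")

  writeLines(c("taxon_id\ts1\ts2", "t1\t1\t2", "t1\t3\t4"), path)
  expect_error(read_count_table(path), "duplicate")

  expect_error(count_table(matrix(-1, 1, 1)), "non-negative")
  expect_error(write_count_table(toy_table(), "/nonexistent-dir/x.tsv"),
               "could not write")
})

test_that("group maps read back and conflicting duplicates error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "s1\tA", "s2\tA", "s3\tB", "s4\tB"), path)
  gm <- read_group_map(path)
  expect_equal(nrow(gm), 4)
  expect_setequal(unique(gm$group), c("A", "B"))

  # exact duplicate rows collapse silently
  writeLines(c("sample_id\tgroup", "s1\tA", "s1\tA", "s2\tB"), path)
  expect_equal(nrow(read_group_map(path)), 2)

  writeLines(c("sample_id\tgroup", "s1\tA", "s1\tB"), path)
  expect_error(read_group_map(path), "conflicting")
})

test_that("resolution collapsing sums clusters and conserves sample totals", {
  tab <- count_table(matrix(c(1L, 2L, 3L), ncol = 1,
                            dimnames = list(c("a", "b", "c"), "s1")))
  hier <- tibble::tibble(taxon_id = c("a", "b", "c"),
                         `99` = c("a", "b", "c"),
                         `97` = c("u", "u", "v"))
  attr(hier, "levels") <- c("99", "97")

  # identity level leaves the table unchanged (up to row order)
  id <- collapse_resolution(tab, hier, "99")
  expect_identical(unclass(id)[rownames(tab), , drop = FALSE], unclass(tab))

  # taxa a & b merge: counts (1,2,3) -> (3,3), total conserved
  merged <- collapse_resolution(tab, hier, "97")
  expect_equal(unname(unclass(merged)[c("u", "v"), 1]), c(3, 3))
  expect_equal(sample_totals(merged), sample_totals(tab))

  # all taxa to one cluster -> single row of column sums
  hier$`90` <- c("all", "all", "all")
  attr(hier, "levels") <- c("99", "97", "90")
  one <- collapse_resolution(tab, hier, "90")
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(unname(unclass(one)[1, 1]), 6)

  expect_error(collapse_resolution(tab, hier, "42"), "unknown resolution")
  expect_error(collapse_resolution(toy_table(), hier, "97"), "missing from hierarchy")
})

test_that("collapsing conserves totals and never increases richness (random tables)", {
  for (seed in 1:5) {
    tab <- random_table(n_taxa = 40, n_samples = 6, seed = seed)
    hier <- make_hierarchy(rownames(tab), seed = seed)
    prev_richness <- colSums(unclass(tab) > 0)
    for (lv in c("99", "97", "95", "90")) {
      coll <- collapse_resolution(tab, hier, lv)
      expect_equal(sample_totals(coll), sample_totals(tab))
      rich <- colSums(unclass(coll) > 0)
      expect_true(all(rich <= prev_richness))
      prev_richness <- rich
    }
  }
})

test_that("hierarchy refinement violations are hard errors at load time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  # cluster u at 97 splits into different 90-level clusters: inconsistent
  writeLines(c("taxon_id\t97\t90", "a\tu\tx", "b\tu\ty"), path)
  expect_error(read_taxonomy_hierarchy(path), "refinement-consistent")

  writeLines(c("taxon_id\t97\t90", "a\tu\tx", "b\tu\tx", "c\tv\tx"), path)
  h <- read_taxonomy_hierarchy(path)
  expect_equal(attr(h, "levels"), c("97", "90"))
})
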