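test_that("hit files map fields and derive translated-search coverage", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "r1\tNiFe_group1h~WP001\t63.2\t45\t2\t0\t1\t135\t10\t54\t1e-12\t71",
    "r2\tCoxL~WP002\t88.0\t40\t1\t0\t1\t120\t5\t44\t1e-20\t95.5"
  ), f)
  hits <- read_hit_table(f, "S1", read_lengths = 140)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$percent_identity[1], 63.2)
  expect_equal(hits$bitscore[1], 71)
  expect_equal(hits$family_id, c("NiFe_group1h", "CoxL"))
  expect_equal(hits$query_coverage[1], 100 * 45 * 3 / 140)
  expect_equal(hits$sample_id, c("S1", "S1"))

  # a 13th qcovhsp column takes precedence over the derived value
  writeLines("r1\tCoxL~WP002\t88.0\t40\t1\t0\t1\t120\t5\t44\t1e-20\t95.5\t91.4", f)
  hits13 <- read_hit_table(f, "S1", read_lengths = 140)
  expect_equal(hits13$query_coverage, 91.4)
})

test_that("empty hit files parse to empty tables without warnings", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_no_warning(hits <- read_hit_table(f, "S1"))
  expect_equal(nrow(hits), 0L)
  expect_equal(attr(hits, "n_skipped"), 0L)
})

test_that("malformed rows fail with the offending line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("r1\tCoxL~x\t88.0\t40\t1\t0\t1\t120\t5\t44\t1e-20", f) # 11 cols
  expect_error(read_hit_table(f, "S1"), "line 1")
})

test_that("unknown family prefixes are skipped, warned about, and counted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "r1\tCoxL~x\t88.0\t40\t1\t0\t1\t120\t5\t44\t1e-20\t95\t92",
    "r2\tNotAFamily~y\t70.0\t40\t1\t0\t1\t120\t5\t44\t1e-20\t80\t92"
  ), f)
  expect_warning(hits <- read_hit_table(f, "S1", registry = default_registry()),
                 "unknown family")
  expect_equal(nrow(hits), 1L)
  expect_equal(attr(hits, "n_skipped"), 1L)
})

test_that("the default registry carries 51 metabolic + 14 ribosomal families", {
  reg <- default_registry()
  expect_equal(sum(!reg$is_single_copy_ribosomal), 51L)
  expect_equal(sum(reg$is_single_copy_ribosomal), 14L)
  expect_equal(reg$identity_threshold[reg$family_id == "CoxL"], 60)
  expect_equal(reg$identity_threshold[reg$family_id == "PsaA"], 80)
  expect_equal(reg$identity_threshold[reg$family_id == "RHO"], 40)
  expect_true(all(reg$identity_threshold %in% c(40, 50, 60, 70, 75, 80)))
})

test_that("registry validation rejects bad thresholds, duplicates, missing columns", {
  reg <- default_registry()
  f <- withr::local_tempfile(fileext = ".tsv")
  bad <- reg
  bad$identity_threshold[1] <- 150
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_marker_registry(f), "identity_threshold")

  dup <- rbind(reg, reg[1, ])
  utils::write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_marker_registry(f), "duplicate")

  utils::write.table(reg[, -2], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_marker_registry(f), "missing column")
})

test_that("tidy results round-trip at full precision and are byte-stable", {
  prof <- expand.grid(sample_id = sprintf("S%02d", 1:24),
                      family_id = default_registry()$family_id,
                      stringsAsFactors = FALSE)
  set.seed(42)
  prof$rpkm <- stats::runif(nrow(prof)) * 100
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- write_tidy_results(list(profile = prof), d1)
  expect_equal(man$tables[[1]]$rows, 24 * 65)
  back <- read_tidy_table(file.path(d1, "profile.tsv"))
  expect_equal(back$rpkm, prof$rpkm)
  expect_equal(back$sample_id, prof$sample_id)
  write_tidy_results(list(profile = prof), d2)
  expect_tsv_identical(file.path(d1, "profile.tsv"), file.path(d2, "profile.tsv"))

  man0 <- write_tidy_results(list(), d2)
  expect_length(man0$tables, 0L)
})
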