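reg <- default_registry()

test_that("filtering applies coverage, identity, and bitscore rules exactly", {
  # CoxL below its 60% threshold despite high coverage
  coxl <- make_hits("r1", "CoxL", identity = 55, coverage = 95, bitscore = 80)
  expect_equal(nrow(filter_hits(coxl, reg)), 0L)
  # PsaA above its 80% identity threshold but at 79% coverage
  psaa <- make_hits("r2", "PsaA", identity = 85, coverage = 79, bitscore = 80)
  expect_equal(nrow(filter_hits(psaa, reg)), 0L)
  # coverage exactly 80 fails for metabolic (strict) but passes for ribosomal
  met80 <- make_hits("r3", "CoxL", identity = 90, coverage = 80, bitscore = 80)
  expect_equal(nrow(filter_hits(met80, reg)), 0L)
  rib80 <- make_hits("r4", "rplB", identity = 90, coverage = 80, bitscore = 40)
  expect_equal(nrow(filter_hits(rib80, reg)), 1L)
  # ribosomal bitscore below 40 fails regardless of identity
  rib39 <- make_hits("r5", "rplB", identity = 99, coverage = 95, bitscore = 39.9)
  expect_equal(nrow(filter_hits(rib39, reg)), 0L)
  # identity exactly at threshold is retained (non-strict)
  at_thr <- make_hits("r6", "CoxL", identity = 60, coverage = 81, bitscore = 80)
  expect_equal(nrow(filter_hits(at_thr, reg)), 1L)
  expect_error(filter_hits(make_hits("r7", "NoSuch", 50, 90, 50), reg),
               "unknown family")
})

test_that("a mixed toy table retains exactly the brute-force set", {
  hits <- rbind(
    make_hits(sprintf("r%d", 1:3), "NiFe_group1h", identity = c(70, 45, 66),
              coverage = c(92, 95, 90), bitscore = c(60, 70, 55)),
    make_hits(sprintf("r%d", 4:6), "CoxL", identity = c(62, 58, 75),
              coverage = c(85, 99, 70), bitscore = c(90, 95, 99)),
    make_hits("r1", "NiFe_group1h", identity = 80, coverage = 91, bitscore = 88),
    make_hits(sprintf("r%d", 8:10), "rplB", identity = c(90, 90, 90),
              coverage = c(80, 85, 95), bitscore = c(45, 80, 50))
  )
  got <- filter_hits(hits, reg)
  want <- brute_filter(hits, reg)
  # 3 below thresholds/coverage drop, r1 deduplicates to its best hit: 6 remain
  expect_equal(nrow(got), 6L)
  key <- function(h) sort(paste(h$read_id, h$family_id, h$bitscore))
  expect_equal(key(got), key(want))
  # the duplicated read keeps its highest-bitscore hit
  expect_equal(got$bitscore[got$read_id == "r1"], 88)
})

test_that("RPKM follows the count / kb / million-reads formula", {
  expect_equal(compute_rpkm(50, 1200, 1e7), 50 / 1.2 / 10, tolerance = 1e-12)
  expect_equal(compute_rpkm(0, 1200, 1e7), 0)
  expect_equal(compute_rpkm(50, 1200, 2e7), compute_rpkm(50, 1200, 1e7) / 2)
  expect_error(compute_rpkm(1, 0, 1e6), "reference_length_bp")
  expect_error(compute_rpkm(1, 100, 0), "n_reads")
})

test_that("the single-copy baseline is the mean of exactly 14 values", {
  expect_equal(single_copy_baseline(rep(48, 14))$baseline_rpkm, 48)
  expect_equal(single_copy_baseline(c(rep(50, 13), 24))$baseline_rpkm,
               (13 * 50 + 24) / 14)
  expect_error(single_copy_baseline(rep(48, 13)), "14")
  expect_true(single_copy_baseline(rep(0, 14))$degenerate)
})

test_that("community fractions divide by the baseline and flag >100% honestly", {
  expect_equal(community_fraction(12, 48)$community_percent, 25)
  expect_equal(community_fraction(48, 48)$community_percent, 100)
  over <- community_fraction(60, 48)
  expect_equal(over$community_percent, 125)  # reported, not truncated
  expect_true(over$capped)
  expect_error(community_fraction(12, 0), "positive")
})

test_that("process aggregation sums member families and caps at 100", {
  prof <- data.frame(sample_id = "S1",
                     family_id = c("NiFe_group1h", "NiFe_group1l", "CoxL"),
                     community_percent = c(22, 60, 10))
  pm <- c(NiFe_group1h = "uptake hydrogenase", NiFe_group1l = "uptake hydrogenase",
          CoxL = "CO oxidation")
  agg <- aggregate_process(prof, pm, rule = "sum")
  expect_equal(agg$process_percent[agg$process == "uptake hydrogenase"], 82)
  expect_equal(agg$process_percent[agg$process == "CO oxidation"], 10)
  # max rule takes the dominant family
  aggm <- aggregate_process(prof, pm, rule = "max")
  expect_equal(aggm$process_percent[aggm$process == "uptake hydrogenase"], 60)
  expect_equal(attr(agg, "rule"), "sum")
  # over-100 sums cap with a flag
  prof$community_percent <- c(80, 50, 10)
  agg2 <- aggregate_process(prof, pm, rule = "sum")
  expect_equal(agg2$process_percent[agg2$process == "uptake hydrogenase"], 100)
  expect_true(agg2$capped[agg2$process == "uptake hydrogenase"])
})

test_that("community percent is invariant to joint count/library scaling", {
  counts <- c(30, 5, 0, 120)
  lens <- c(1800, 2370, 750, 819)
  for (fac in c(1, 2, 10)) {
    rpkm <- compute_rpkm(counts * fac, lens, 1e6 * fac)
    pct <- 100 * rpkm[1] / rpkm[4]
    if (fac == 1) ref <- pct
    expect_equal(pct, ref, tolerance = 1e-12)
  }
})

test_that("estimator recovers carriage on synthetic data and sees 2-copy bias", {
  ests <- vapply(1:8, function(r) {
    comm <- simulate_community(100, c(NiFe_group1l = 0.25), seed = 100 + r)
    ht <- simulate_hit_tables(comm, 1e6, seed = 200 + r)
    pr <- profile_sample(ht$hits, reg, ht$library)
    pr$community_percent[pr$family_id == "NiFe_group1l"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 25), 2)

  # genomes carrying 2 copies inflate the estimate ~2-fold
  comm2 <- simulate_community(100, c(NiFe_group1l = 0.25), copy_number = 2L,
                              seed = 31)
  ht2 <- simulate_hit_tables(comm2, 2e6, seed = 32)
  pr2 <- profile_sample(ht2$hits, reg, ht2$library)
  est2 <- pr2$community_percent[pr2$family_id == "NiFe_group1l"]
  expect_equal(est2 / 25, 2, tolerance = 0.2)
})

test_that("pipeline tallies equal brute-force tallies on fuzzed tables", {
  for (r in 1:15) {
    hits <- random_hits(reg, n = 120, seed = 400 + r)
    lib <- data.frame(sample_id = "S1", n_reads = 1e6,
                      mean_read_length_bp = 140, zone = "arid",
                      stratum = "topsoil")
    kept <- brute_filter(hits, reg)
    counts <- brute_counts(kept, reg)
    rib <- reg$is_single_copy_ribosomal
    baseline <- mean(counts[rib] / (reg$reference_length_bp[rib] / 1000) /
                       (lib$n_reads / 1e6))
    if (baseline == 0) next
    pr <- profile_sample(hits, reg, lib)
    expect_equal(pr$read_count, unname(counts[pr$family_id]))
    expect_equal(attr(pr, "baseline_rpkm"), baseline, tolerance = 1e-12)
  }
})

test_that("MAG prevalence adjusts for genome completeness", {
  mags <- data.frame(mag_id = sprintf("m%02d", 1:10),
                     phylum = rep(c("Actinobacteriota", "Cyanobacteria"), 5),
                     completeness = rep(70, 10), contamination = 5,
                     HhyL = c(rep(TRUE, 4), rep(FALSE, 6)))
  got <- mag_prevalence(mags, "HhyL", group_by = "all")
  expect_equal(got$raw_percent, 40)
  expect_equal(got$adjusted_percent, 100 * 4 / 7, tolerance = 1e-12)

  mags$completeness <- 100
  same <- mag_prevalence(mags, "HhyL")
  expect_equal(same$adjusted_percent, same$raw_percent)

  set.seed(9)
  mags$completeness <- runif(10, 55, 99)
  mixed <- mag_prevalence(mags, "HhyL")
  expect_equal(mixed$adjusted_percent,
               100 * 4 / sum(mags$completeness / 100), tolerance = 1e-12)
  by_phy <- mag_prevalence(mags, "HhyL", group_by = "phylum")
  expect_equal(nrow(by_phy), 2L)
  expect_error(mag_prevalence(mags[0, ], "HhyL"), "empty")
})
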