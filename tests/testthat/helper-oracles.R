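# Independent brute-force oracles and small fixture builders shared across
# test files. Oracles are deliberately written as plain row-by-row loops so
# they stay independent of the vectorized implementation paths they check.

make_hits <- function(read_id, family_id, identity, coverage, bitscore,
                      sample_id = "S1", accession = NULL) {
  n <- max(length(read_id), length(family_id), length(identity))
  if (is.null(accession)) accession <- sprintf("acc%03d", seq_len(n))
  data.frame(
    read_id = rep_len(read_id, n),
    family_id = rep_len(family_id, n),
    subject_id = paste0(rep_len(family_id, n), "~", rep_len(accession, n)),
    percent_identity = rep_len(identity, n),
    query_coverage = rep_len(coverage, n),
    bitscore = rep_len(bitscore, n),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

# Row-by-row application of the published filtering rule, then best-bitscore
# deduplication per (read, family) by explicit search.
brute_filter <- function(hits, registry) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    fam <- registry[registry$family_id == hits$family_id[i], ]
    keep[i] <- if (fam$is_single_copy_ribosomal) {
      hits$query_coverage[i] >= 80 && hits$bitscore[i] >= 40
    } else {
      hits$query_coverage[i] > 80 &&
        hits$percent_identity[i] >= fam$identity_threshold
    }
  }
  kept <- hits[keep, , drop = FALSE]
  out <- kept[0, , drop = FALSE]
  for (key in unique(paste(kept$read_id, kept$family_id))) {
    rows <- kept[paste(kept$read_id, kept$family_id) == key, , drop = FALSE]
    out <- rbind(out, rows[which.max(rows$bitscore), , drop = FALSE])
  }
  out
}

brute_counts <- function(kept, registry) {
  counts <- integer(nrow(registry))
  names(counts) <- registry$family_id
  for (i in seq_len(nrow(kept))) {
    counts[kept$family_id[i]] <- counts[kept$family_id[i]] + 1L
  }
  counts
}

# Random hit table over the full registry for fuzzing; identities and
# coverages straddle the thresholds so filtering is exercised.
random_hits <- function(registry, n, seed, sample_id = "S1") {
  set.seed(seed)
  fam <- sample(registry$family_id, n, replace = TRUE)
  thr <- registry$identity_threshold[match(fam, registry$family_id)]
  make_hits(
    read_id = sprintf("r%05d", sample.int(n * 2, n, replace = TRUE)),
    family_id = fam,
    identity = pmin(pmax(thr + stats::rnorm(n, 0, 10), 0), 100),
    coverage = stats::runif(n, 60, 100),
    bitscore = stats::runif(n, 20, 150),
    sample_id = sample_id
  )
}

# All orderings of 1..n (small n), for exact permutation-test oracles.
enumerate_orderings <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- enumerate_orderings(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}

# Between/within decomposition of squared dissimilarities, written
# independently of the package internals.
brute_pseudo_f <- function(d, groups) {
  n <- nrow(d)
  lv <- unique(groups)
  ss <- function(ix) {
    tot <- 0
    for (i in ix) for (j in ix) tot <- tot + d[i, j]^2
    tot / (2 * length(ix))
  }
  ss_t <- ss(seq_len(n))
  ss_w <- sum(vapply(lv, function(g) ss(which(groups == g)), numeric(1)))
  ((ss_t - ss_w) / (length(lv) - 1)) / (ss_w / (n - length(lv)))
}

expect_tsv_identical <- function(path1, path2) {
  expect_identical(unname(tools::md5sum(path1)), unname(tools::md5sum(path2)))
}
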