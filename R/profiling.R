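#' Filter marker hits by coverage, identity, and bitscore rules
#'
#' Metabolic-family hits are retained iff query coverage > 80% and percent
#' identity is at or above the family-specific threshold. Hits to the 14
#' single-copy ribosomal genes are retained iff query coverage >= 80% and
#' bitscore >= 40 (their searches are bitscore-thresholded, not
#' identity-thresholded). The coverage comparison is strict for metabolic
#' families and non-strict for ribosomal families, mirroring the two rules;
#' the identity comparison is non-strict at the threshold. When one read has
#' several retained hits to the same family, only the highest-bitscore hit
#' is kept (ties broken by first occurrence), preventing multi-HSP double
#' counting.
#'
#' @param hits Hit data frame (see [read_hit_table()]).
#' @param registry Marker registry covering every `family_id` in `hits`.
#' @return The retained hits, one row per read per family.
#' @export
filter_hits <- function(hits, registry) {
  if (nrow(hits) == 0L) return(hits)
  idx <- match(hits$family_id, registry$family_id)
  if (anyNA(idx)) {
    stop("hits reference unknown family_id: ",
         paste(unique(hits$family_id[is.na(idx)]), collapse = ", "))
  }
  thr <- registry$identity_threshold[idx]
  is_rib <- registry$is_single_copy_ribosomal[idx]
  keep <- ifelse(is_rib,
                 hits$query_coverage >= 80 & hits$bitscore >= 40,
                 hits$query_coverage > 80 & hits$percent_identity >= thr)
  keep[is.na(keep)] <- FALSE
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) > 1L) {
    ord <- order(out$read_id, out$family_id, -out$bitscore)
    out <- out[ord, , drop = FALSE]
    dup <- duplicated(out[, c("read_id", "family_id")])
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Reads per kilobase of reference per million library reads
#'
#' `rpkm = read_count / (reference_length_bp / 1000) / (n_reads / 1e6)`,
#' normalizing marker-gene read counts for reference length and sequencing
#' depth. Vectorized over all arguments.
#'
#' @param read_count Retained read count (>= 0).
#' @param reference_length_bp Reference length in bp (> 0).
#' @param n_reads Library size (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(read_count, reference_length_bp, n_reads) {
  if (any(reference_length_bp <= 0)) stop("reference_length_bp must be > 0")
  if (any(n_reads <= 0)) stop("n_reads must be > 0")
  read_count / (reference_length_bp / 1000) / (n_reads / 1e6)
}

#' Single-copy ribosomal baseline for one sample
#'
#' The arithmetic mean RPKM of exactly 14 universal single-copy ribosomal
#' genes (zeros included) gives the abundance of a gene carried once by 100%
#' of community members; it is the denominator of the community-fraction
#' estimator.
#'
#' @param ribosomal_rpkm Numeric vector of exactly 14 RPKM values.
#' @param sample_id Sample identifier.
#' @return List with `sample_id`, `baseline_rpkm`, and `degenerate` flag
#'   (TRUE when the baseline is 0, in which case downstream fractions are
#'   undefined for the sample).
#' @export
single_copy_baseline <- function(ribosomal_rpkm, sample_id = NA_character_) {
  if (length(ribosomal_rpkm) != 14L) {
    stop("expected exactly 14 ribosomal RPKM values, got ", length(ribosomal_rpkm))
  }
  b <- mean(ribosomal_rpkm)
  list(sample_id = sample_id, baseline_rpkm = b, degenerate = b == 0)
}

#' Percentage of the community encoding a gene family
#'
#' `percent = 100 * family_rpkm / baseline_rpkm`, assuming one copy per
#' genome. Values above 100 are reported as-is with a `capped` flag, never
#' truncated: they indicate multi-copy carriage or estimation noise.
#'
#' @param family_rpkm Family RPKM (vectorized).
#' @param baseline A baseline from [single_copy_baseline()], or a single
#'   positive number.
#' @return Data frame with `community_percent` and `capped` columns.
#' @export
community_fraction <- function(family_rpkm, baseline) {
  b <- if (is.list(baseline)) baseline$baseline_rpkm else baseline
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    stop("baseline_rpkm must be a single positive number; ",
         "community fraction is undefined for this sample")
  }
  pct <- 100 * family_rpkm / b
  data.frame(community_percent = pct, capped = pct > 100)
}

#' Profile one sample: counts, RPKM, baseline, and community percentages
#'
#' Runs the full per-sample chain: filter hits, tally retained reads per
#' family (zero-count families included), convert to RPKM with per-family
#' reference lengths, average the 14 ribosomal families into the single-copy
#' baseline, and express each metabolic family as a percentage of community
#' members encoding it.
#'
#' @param hits Hit data frame for one sample.
#' @param registry Marker registry.
#' @param library One-row library data frame (`sample_id`, `n_reads`, ...).
#' @return Data frame over metabolic families: sample_id, family_id,
#'   read_count, rpkm, community_percent, capped; the baseline is attached
#'   as attribute `baseline_rpkm`.
#' @export
profile_sample <- function(hits, registry, library) {
  stopifnot(nrow(library) == 1L, library$n_reads > 0)
  kept <- filter_hits(hits, registry)
  counts <- table(factor(kept$family_id, levels = registry$family_id))
  counts <- as.integer(counts)
  rpkm <- compute_rpkm(counts, registry$reference_length_bp, library$n_reads)
  rib <- registry$is_single_copy_ribosomal
  base <- single_copy_baseline(rpkm[rib], library$sample_id)
  met <- !rib
  if (base$degenerate) {
    stop("single-copy baseline is zero for sample ", library$sample_id,
         "; community fractions undefined")
  }
  frac <- community_fraction(rpkm[met], base)
  out <- data.frame(
    sample_id = library$sample_id,
    family_id = registry$family_id[met],
    read_count = counts[met],
    rpkm = rpkm[met],
    community_percent = frac$community_percent,
    capped = frac$capped,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sample_id, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_rpkm") <- base$baseline_rpkm
  out
}

#' Aggregate family-level community percentages into processes
#'
#' Estimates the percentage of the community encoding at least one gene of a
#' process. Default rule: the sum of member-family percentages, capped at
#' 100 (families of a process tend to occur in different genomes, so the sum
#' approximates a union); alternative rule `"max"` takes the largest member
#' family (a lower bound). The rule used is recorded in the `rule` attribute
#' so output manifests can carry it.
#'
#' @param profile Profile data frame from [profile_sample()] (one or more
#'   samples bound together).
#' @param process_map Named character vector mapping family_id -> process;
#'   defaults to the registry's `process` column.
#' @param rule `"sum"` (default) or `"max"`.
#' @return Data frame: sample_id, process, process_percent, capped.
#' @export
aggregate_process <- function(profile, process_map = NULL, rule = c("sum", "max")) {
  rule <- match.arg(rule)
  if (is.null(process_map)) {
    reg <- default_registry()
    process_map <- stats::setNames(reg$process, reg$family_id)
  }
  unknown <- setdiff(unique(profile$family_id), names(process_map))
  if (length(unknown) > 0L) {
    stop("process_map does not cover families: ", paste(unknown, collapse = ", "))
  }
  proc <- unname(process_map[profile$family_id])
  agg_fun <- if (rule == "sum") sum else max
  agg <- stats::aggregate(profile$community_percent,
                          by = list(sample_id = profile$sample_id, process = proc),
                          FUN = agg_fun)
  names(agg)[3L] <- "raw_percent"
  agg$process_percent <- pmin(agg$raw_percent, 100)
  agg$capped <- agg$raw_percent > 100
  agg <- agg[order(agg$sample_id, agg$process), c("sample_id", "process",
                                                  "process_percent", "capped")]
  rownames(agg) <- NULL
  attr(agg, "rule") <- rule
  agg
}

#' MAG prevalence of a gene family, raw and completeness-adjusted
#'
#' Raw prevalence is the percentage of MAGs encoding the family. Because
#' draft genomes are incomplete, a gene absent from a MAG may simply be
#' unassembled; the adjusted prevalence divides by the summed completeness
#' (as a fraction) instead of the genome count:
#' `adjusted = 100 * n_with_gene / sum(completeness / 100)`.
#'
#' @param mags Data frame with columns `mag_id`, `phylum`, `completeness`
#'   (percent, in (50, 100\]), `contamination` (< 10), and one logical column
#'   per family.
#' @param family_id Family column to assess.
#' @param group_by `"all"` or `"phylum"`.
#' @return Data frame: group, n_mags, n_with_gene, raw_percent,
#'   adjusted_percent.
#' @export
mag_prevalence <- function(mags, family_id, group_by = c("all", "phylum")) {
  group_by <- match.arg(group_by)
  if (nrow(mags) == 0L) stop("empty MAG set")
  if (!family_id %in% names(mags)) stop("unknown family column: ", family_id)
  if (any(mags$completeness <= 50 | mags$completeness > 100)) {
    stop("MAG completeness must lie in (50, 100]")
  }
  if (any(mags$contamination >= 10)) stop("MAG contamination must be < 10")
  grp <- if (group_by == "all") rep("all", nrow(mags)) else mags$phylum
  pos <- as.logical(mags[[family_id]])
  out <- do.call(rbind, lapply(split(seq_len(nrow(mags)), grp), function(ix) {
    data.frame(group = grp[ix[1L]], n_mags = length(ix),
               n_with_gene = sum(pos[ix]),
               raw_percent = 100 * sum(pos[ix]) / length(ix),
               adjusted_percent = 100 * sum(pos[ix]) /
                 sum(mags$completeness[ix] / 100),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
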