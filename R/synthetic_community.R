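#' Simulate a soil community with known gene content
#'
#' Constructs a community of genomes with known relative abundances and
#' marker-gene complements, the ground truth against which the read-based
#' community-fraction estimator is validated. For each metabolic family the
#' number of carrier genomes is `round(carrier_fraction * n_genomes)`
#' (half-to-even rounding, R's default); carriers are drawn at random.
#' Every genome carries exactly one copy of each of the 14 single-copy
#' ribosomal genes, the assumption the estimator relies on.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param carrier_fraction Named numeric vector, fraction of genomes carrying
#'   each family (values in \[0, 1\]); names must be registry family ids.
#' @param abundance_model `"uniform"` (equal abundances) or `"lognormal"`
#'   (log-normal abundances with log-sd `sigma`, renormalized).
#' @param sigma Log-sd for the lognormal abundance model.
#' @param copy_number Copies carried per carrier genome (default 1; use 2 to
#'   study multi-copy bias).
#' @param genome_size_bp Genome size in bp (single value or length
#'   `n_genomes`); default 3 Mb, typical of soil Actinobacteriota.
#' @param registry Marker registry; ribosomal families are taken from it.
#' @param seed Integer seed; the community is a pure function of the
#'   arguments and this seed.
#' @return An object of class `synthetic_community`: list with `genomes`
#'   (data frame: genome_id, relative_abundance, genome_size_bp),
#'   `gene_complement` (genomes x families integer matrix),
#'   `true_fraction` (named vector: abundance-weighted fraction of the
#'   community carrying each metabolic family), and `seed`.
#' @export
simulate_community <- function(n_genomes, carrier_fraction,
                               abundance_model = c("uniform", "lognormal"),
                               sigma = 1, copy_number = 1L,
                               genome_size_bp = 3e6,
                               registry = default_registry(), seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_genomes >= 1, length(carrier_fraction) > 0,
            !is.null(names(carrier_fraction)))
  if (any(carrier_fraction < 0 | carrier_fraction > 1)) {
    stop("carrier_fraction values must lie in [0, 1]")
  }
  unknown <- setdiff(names(carrier_fraction), registry$family_id)
  if (length(unknown) > 0L) {
    stop("carrier_fraction names absent from registry: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  ab <- switch(abundance_model,
               uniform = rep(1 / n_genomes, n_genomes),
               lognormal = {
                 x <- stats::rlnorm(n_genomes, meanlog = 0, sdlog = sigma)
                 x / sum(x)
               })
  size <- rep_len(genome_size_bp, n_genomes)
  rib <- registry$family_id[registry$is_single_copy_ribosomal]
  fams <- c(names(carrier_fraction), rib)
  comp <- matrix(0L, nrow = n_genomes, ncol = length(fams),
                 dimnames = list(sprintf("g%04d", seq_len(n_genomes)), fams))
  comp[, rib] <- 1L
  for (f in names(carrier_fraction)) {
    n_carrier <- round(carrier_fraction[[f]] * n_genomes)
    if (n_carrier > 0L) {
      carriers <- sample.int(n_genomes, n_carrier)
      comp[carriers, f] <- as.integer(copy_number)
    }
  }
  truth <- vapply(names(carrier_fraction),
                  function(f) sum(ab[comp[, f] > 0L]), numeric(1))
  out <- list(
    genomes = data.frame(genome_id = rownames(comp), relative_abundance = ab,
                         genome_size_bp = size, stringsAsFactors = FALSE),
    gene_complement = comp,
    true_fraction = truth,
    seed = seed
  )
  class(out) <- "synthetic_community"
  out
}

#' Simulate a per-sample marker hit table from a community
#'
#' Emulates a translated homology search of `n_reads` short reads against the
#' marker databases. For each family the expected on-target hit count is
#' `n_reads * sum_g(ab_g * copies_g * reference_length_bp) /
#' sum_g(ab_g * genome_size_bp)` (the fraction of sequenced bases falling in
#' that gene), realized as a Poisson draw. Hit identities are drawn around
#' the family threshold + 15 points (sd `identity_noise_sd`) and clamped
#' above the threshold so that, at `decoy_rate = 0`, every generated hit
#' passes [filter_hits()]. Decoy hits (an additional `decoy_rate` fraction)
#' are drawn strictly below the family threshold and labelled `DECOY` in the
#' accession part of `subject_id`, so filtering tests are exact.
#'
#' @param community A `synthetic_community`.
#' @param n_reads Library size (forward reads searched).
#' @param read_length_bp Mean read length (default 140 bp).
#' @param registry Marker registry covering all families in the community.
#' @param identity_noise_sd Sd of the identity noise, percentage points.
#' @param decoy_rate Fraction of additional below-threshold hits.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @param zone,stratum Labels recorded in the library table.
#' @return List with `hits` (data frame as from [read_hit_table()]) and
#'   `library` (one-row data frame: sample_id, n_reads, mean_read_length_bp,
#'   zone, stratum).
#' @export
simulate_hit_tables <- function(community, n_reads, read_length_bp = 140,
                                registry = default_registry(),
                                identity_noise_sd = 3, decoy_rate = 0,
                                seed = 1L, sample_id = "S1",
                                zone = "arid", stratum = "topsoil") {
  stopifnot(inherits(community, "synthetic_community"), n_reads > 0)
  comp <- community$gene_complement
  missing <- setdiff(colnames(comp), registry$family_id)
  if (length(missing) > 0L) {
    stop("registry does not cover families: ", paste(missing, collapse = ", "))
  }
  set.seed(seed)
  ab <- community$genomes$relative_abundance
  gsize <- community$genomes$genome_size_bp
  denom <- sum(ab * gsize)
  fams <- colnames(comp)
  idx <- match(fams, registry$family_id)
  ref_len <- registry$reference_length_bp[idx]
  thr <- registry$identity_threshold[idx]
  is_rib <- registry$is_single_copy_ribosomal[idx]

  lambda <- n_reads * as.numeric(crossprod(comp, ab)) * ref_len / denom
  counts <- stats::rpois(length(lambda), lambda)
  n_decoy <- if (decoy_rate > 0) stats::rpois(length(lambda), decoy_rate * lambda)
             else integer(length(lambda))

  mk_hits <- function(n_per_fam, decoy) {
    total <- sum(n_per_fam)
    if (total == 0L) return(empty_hit_table(sample_id))
    fam <- rep(fams, n_per_fam)
    t_fam <- rep(thr, n_per_fam)
    rib_fam <- rep(is_rib, n_per_fam)
    if (decoy) {
      # below the discriminating threshold of each family class: identity for
      # metabolic families, bitscore for the ribosomal set
      ident <- pmax(t_fam - stats::runif(total, 5, 25), 0)
      acc <- sprintf("DECOY%06d", seq_len(total))
      bits <- ifelse(rib_fam, stats::runif(total, 10, 39.5),
                     stats::runif(total, 45, 150))
    } else {
      ident <- pmin(pmax(t_fam + 15 + stats::rnorm(total, 0, identity_noise_sd),
                         t_fam + 0.01), 100)
      acc <- sprintf("ref%06d", seq_len(total))
      bits <- stats::runif(total, 45, 150)
    }
    qcov <- ifelse(rib_fam, stats::runif(total, 80, 100), stats::runif(total, 85, 100))
    data.frame(
      read_id = sprintf("%s_read%07d", sample_id,
                        sample.int(.Machine$integer.max %/% 2, total)),
      family_id = fam,
      subject_id = paste0(fam, "~", acc),
      percent_identity = round(ident, 1),
      query_coverage = round(qcov, 1),
      bitscore = round(bits, 1),
      sample_id = sample_id,
      stringsAsFactors = FALSE
    )
  }
  hits <- rbind(mk_hits(counts, decoy = FALSE), mk_hits(n_decoy, decoy = TRUE))
  rownames(hits) <- NULL
  lib <- data.frame(sample_id = sample_id, n_reads = n_reads,
                    mean_read_length_bp = read_length_bp,
                    zone = zone, stratum = stratum, stringsAsFactors = FALSE)
  list(hits = hits, library = lib)
}

#' Write a simulated hit table in 13-column BLAST tabular layout
#'
#' Serializes hits produced by [simulate_hit_tables()] into the same file
#' format [read_hit_table()] parses (outfmt-6 plus a qcovhsp column), for
#' file-based pipeline runs.
#'
#' @param hits Hit data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  n <- nrow(hits)
  tab <- data.frame(
    qseqid = hits$read_id, sseqid = hits$subject_id,
    pident = hits$percent_identity, length = 50L, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 140L, sstart = 1L, send = 50L,
    evalue = rep("1e-10", n), bitscore = hits$bitscore,
    qcovhsp = hits$query_coverage, stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}
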