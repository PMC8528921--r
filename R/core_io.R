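#' @keywords internal
"_PACKAGE"

#' Read a BLAST-style tabular hit file
#'
#' Parses a 12- or 13-column tab-separated homology search output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore [qcovhsp]`), the output boundary for translated searches of
#' metagenomic reads against marker protein databases. The marker family of
#' each hit is carried in the subject identifier under the convention
#' `FAMILY~accession`.
#'
#' Query coverage is taken from the optional 13th column when present.
#' Otherwise, if read lengths are supplied, it is computed for translated
#' searches as `100 * alignment_length * 3 / read_length_bp`; without either,
#' coverage is `NA` and must be supplied before filtering.
#'
#' @param path Path to the hit file.
#' @param sample_id Sample identifier attached to every hit.
#' @param read_lengths Optional read lengths in bp: a single number applied to
#'   all reads, or a named vector keyed by read id.
#' @param registry Optional marker registry (see [read_marker_registry()]).
#'   When given, hits whose family prefix is absent from the registry are
#'   skipped with a warning; the number skipped is recorded in the
#'   `n_skipped` attribute.
#' @return A data frame of hits with columns `read_id`, `family_id`,
#'   `subject_id`, `percent_identity`, `query_coverage`, `bitscore`,
#'   `sample_id`, and attribute `n_skipped`.
#' @export
read_hit_table <- function(path, sample_id, read_lengths = NULL, registry = NULL) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- empty_hit_table(sample_id)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L & nf != 13L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed hit row at line %d of '%s': expected 12 or 13 columns, found %d",
                 line_no[bad[1L]], path, nf[bad[1L]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, seq_len(12L))), ncol = 12L, byrow = TRUE)
  read_id <- m[, 1L]
  subject_id <- m[, 2L]
  pident <- as.numeric(m[, 3L])
  alen <- as.numeric(m[, 4L])
  bitscore <- as.numeric(m[, 12L])
  if (anyNA(pident) || anyNA(alen) || anyNA(bitscore)) {
    bad <- which(is.na(pident) | is.na(alen) | is.na(bitscore))[1L]
    stop(sprintf("malformed hit row at line %d of '%s': non-numeric field",
                 line_no[bad], path))
  }
  if (any(nf == 13L)) {
    qcov <- rep(NA_real_, length(lines))
    has13 <- nf == 13L
    qcov[has13] <- as.numeric(vapply(fields[has13], `[`, "", 13L))
  } else {
    qcov <- rep(NA_real_, length(lines))
  }
  if (is.null(read_lengths)) {
    fill <- rep(NA_real_, length(read_id))
  } else if (is.null(names(read_lengths))) {
    stopifnot(length(read_lengths) == 1L)
    fill <- 100 * alen * 3 / read_lengths
  } else {
    fill <- 100 * alen * 3 / unname(read_lengths[read_id])
  }
  qcov <- ifelse(is.na(qcov), fill, qcov)

  family_id <- sub("~.*$", "", subject_id)
  hits <- data.frame(
    read_id = read_id, family_id = family_id, subject_id = subject_id,
    percent_identity = pident, query_coverage = qcov, bitscore = bitscore,
    sample_id = sample_id, stringsAsFactors = FALSE
  )
  n_skipped <- 0L
  if (!is.null(registry)) {
    known <- hits$family_id %in% registry$family_id
    n_skipped <- sum(!known)
    if (n_skipped > 0L) {
      warning(sprintf("%d hit(s) with unknown family prefix skipped in '%s'",
                      n_skipped, path))
      hits <- hits[known, , drop = FALSE]
      rownames(hits) <- NULL
    }
  }
  validate_hits(hits)
  attr(hits, "n_skipped") <- n_skipped
  hits
}

empty_hit_table <- function(sample_id = character(0)) {
  data.frame(
    read_id = character(0), family_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), query_coverage = numeric(0),
    bitscore = numeric(0), sample_id = character(0), stringsAsFactors = FALSE
  )
}

validate_hits <- function(hits) {
  pid <- hits$percent_identity
  if (any(pid < 0 | pid > 100, na.rm = TRUE)) {
    stop("percent_identity outside [0, 100]")
  }
  if (any(hits$bitscore < 0, na.rm = TRUE)) stop("negative bitscore")
  invisible(hits)
}

#' Read a marker-family registry
#'
#' The registry lists each marker gene family with its metabolic process
#' label, the gene-specific amino-acid identity threshold used for read
#' filtering, the nucleotide reference length used for RPKM, and whether the
#' family belongs to the set of 14 universal single-copy ribosomal genes that
#' anchors the community-fraction estimator.
#'
#' @param path Path to a tab-separated registry with header columns
#'   `family_id`, `process`, `identity_threshold`, `reference_length_bp`,
#'   `is_single_copy_ribosomal`.
#' @return Validated registry data frame.
#' @export
read_marker_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("family_id", "process", "identity_threshold",
              "reference_length_bp", "is_single_copy_ribosomal")
  missing <- setdiff(needed, names(reg))
  if (length(missing) > 0L) {
    stop("registry missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reg$family_id)) {
    stop("duplicate family_id in registry: ",
         paste(unique(reg$family_id[duplicated(reg$family_id)]), collapse = ", "))
  }
  if (any(reg$identity_threshold < 0 | reg$identity_threshold > 100)) {
    stop("identity_threshold outside [0, 100]")
  }
  if (any(reg$reference_length_bp <= 0)) stop("reference_length_bp must be > 0")
  reg$is_single_copy_ribosomal <- as.logical(reg$is_single_copy_ribosomal)
  if (anyNA(reg$is_single_copy_ribosomal)) {
    stop("is_single_copy_ribosomal must be TRUE/FALSE")
  }
  reg
}

#' Load the default marker registry shipped with the package
#'
#' A package-constructed registry of 51 metabolic marker families (named
#' after the field's standard marker genes, with identity thresholds in the
#' published classes: 60% for NxrA/AmoA/CoxL/group-4 [NiFe]- and
#' [FeFe]-hydrogenases, 70% for PsbA and IsoA, 75% for HbsT, 80% for PsaA,
#' 40% for energy-converting rhodopsins, 50% otherwise) plus 14 universal
#' single-copy ribosomal protein genes. Reference lengths are three times a
#' typical protein length for each family.
#'
#' @return Registry data frame of 65 families.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "marker_registry.tsv", package = "desertprod")
  reg <- read_marker_registry(path)
  stopifnot(sum(reg$is_single_copy_ribosomal) == 14L,
            sum(!reg$is_single_copy_ribosomal) == 51L)
  reg
}

#' Write a set of tidy result tables with a manifest
#'
#' Writes one TSV per table (tab separator, "." decimal, UTF-8, LF line
#' endings, no quoting) plus a JSON manifest recording file names, row
#' counts, package version, and the seeds used by the producing run. Given
#' identical tables the output is byte-identical across runs.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory, created if needed.
#' @param seeds Optional named list/vector of seeds to record.
#' @return The manifest, invisibly.
#' @export
write_tidy_results <- function(tables, out_dir, seeds = NULL) {
  stopifnot(is.list(tables))
  if (length(tables) > 0L && (is.null(names(tables)) || any(!nzchar(names(tables))))) {
    stop("tables must be named")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    stopifnot(is.data.frame(tab))
    file <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(file, open = "wb")
    on.exit(close(con))
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n", fileEncoding = "UTF-8")
    list(name = nm, file = basename(file), rows = nrow(tab), cols = ncol(tab))
  })
  manifest <- list(
    pipeline = "desertprod",
    version = as.character(utils::packageVersion("desertprod")),
    seeds = seeds,
    tables = entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a tidy result table written by [write_tidy_results()]
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_tidy_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
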