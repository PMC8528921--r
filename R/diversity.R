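#' Rarefy an OTU table to a fixed depth
#'
#' Per sample, draws `depth` reads without replacement from the sample's
#' counts (a single seeded multivariate hypergeometric draw, not an average
#' over draws). Samples whose total falls below the depth are dropped with a
#' warning.
#'
#' @param counts Samples x taxa matrix of nonnegative integer counts with
#'   dimnames.
#' @param depth Target depth (> 0).
#' @param seed Integer seed.
#' @return Rarefied samples x taxa matrix; every retained row sums to
#'   exactly `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  check_otu(counts)
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) with fewer than %d reads: %s",
                    sum(!keep), depth,
                    paste(rownames(counts)[!keep], collapse = ", ")))
  }
  counts <- counts[keep, , drop = FALSE]
  set.seed(seed)
  out <- t(apply(counts, 1L, function(x) {
    picked <- sample(rep.int(seq_along(x), x), depth)
    tabulate(picked, nbins = length(x))
  }))
  dimnames(out) <- dimnames(counts)
  storage.mode(out) <- "integer"
  out
}

check_otu <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate sample or taxon labels")
  }
  invisible(counts)
}

#' Chao1 richness estimate for one sample
#'
#' Nonparametric richness from singleton (F1) and doubleton (F2) counts.
#' Bias-corrected form (default): `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`,
#' defined for all inputs. Classic form: `S_obs + F1^2 / (2 F2)`, which is
#' undefined at F2 = 0 and then falls back to the bias-corrected form.
#'
#' @param x Nonnegative integer counts for one sample.
#' @param variant `"bias_corrected"` (default) or `"classic"`.
#' @return Estimated richness.
#' @export
chao1 <- function(x, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  if (any(x < 0) || any(x != round(x))) stop("counts must be nonnegative integers")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (variant == "classic" && f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over taxa, for every pair of
#' samples; 0 for identical samples, 1 for disjoint support.
#'
#' @param counts Samples x taxa abundance matrix (>= 2 samples).
#' @return Symmetric dissimilarity matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
bray_curtis <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) >= 2L)
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      den <- sum(counts[i, ] + counts[j, ])
      if (den == 0) {
        stop(sprintf("Bray-Curtis undefined for all-zero sample pair (%d, %d)", i, j))
      }
      d[i, j] <- d[j, i] <- sum(abs(counts[i, ] - counts[j, ])) / den
    }
  }
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of `-0.5 * D^2`, eigendecomposition, and
#' coordinates `eigenvector * sqrt(eigenvalue)` for positive eigenvalues.
#' Negative eigenvalues (semi-metric distances such as Bray-Curtis) are
#' reported but excluded from the coordinates. Axis signs are fixed by
#' making each axis's largest-magnitude loading positive, so ordinations
#' are reproducible across platforms.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of requested axes (default 2); truncated with a warning
#'   if it exceeds the number of positive eigenvalues.
#' @return List: `points` (n x k' coordinates), `eigenvalues` (all n, sorted
#'   decreasing), `negative_eigenvalues`.
#' @export
pcoa <- function(d, k = 2L) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            max(abs(d - t(d))) < 1e-8, all(abs(diag(d)) < 1e-12))
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-9
  pos <- which(vals > tol)
  if (k > length(pos)) {
    warning(sprintf("only %d positive eigenvalue(s); truncating from k = %d",
                    length(pos), k))
    k <- length(pos)
  }
  use <- pos[seq_len(k)]
  pts <- eig$vectors[, use, drop = FALSE] %*% diag(sqrt(vals[use]), nrow = k)
  for (ax in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, ax]))
    if (pts[i_max, ax] < 0) pts[, ax] <- -pts[, ax]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = vals,
       negative_eigenvalues = vals[vals < -tol])
}

permanova_f <- function(d2, idx, a, n) {
  ss_t <- sum(d2) / (2 * n)
  ss_w <- 0
  for (ix in idx) ss_w <- ss_w + sum(d2[ix, ix]) / (2 * length(ix))
  ss_a <- ss_t - ss_w
  (ss_a / (a - 1)) / (ss_w / (n - a))
}

all_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- all_permutations(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from within- and between-group sums of squared dissimilarities
#' (`SS_T = sum(d^2)/n` over pairs; `SS_W` summed within groups); the
#' p-value is `(1 + #[F_perm >= F_obs]) / (1 + n_perm)` over seeded raw
#' label permutations. With `n_perm = "all"` all `n!` label orderings are
#' enumerated (small n only) and the p-value is the exact fraction of
#' orderings with `F >= F_obs`.
#'
#' @param d Dissimilarity matrix.
#' @param groups Group labels (>= 2 groups, each with >= 2 members).
#' @param n_perm Number of permutations (default 999) or `"all"`.
#' @param seed Integer seed for the permutations.
#' @return List: `pseudo_f`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- as.factor(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n, nlevels(droplevels(groups)) >= 2L)
  groups <- droplevels(groups)
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  d2 <- d^2
  a <- nlevels(groups)
  idx <- split(seq_len(n), groups)
  f_obs <- permanova_f(d2, idx, a, n)
  if (identical(n_perm, "all")) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(seq_len(n))
    f_all <- vapply(perms, function(p) {
      permanova_f(d2, split(p, groups), a, n)
    }, numeric(1))
    return(list(pseudo_f = f_obs,
                p_value = mean(f_all >= f_obs - 1e-12),
                n_perm = length(perms)))
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (permanova_f(d2, split(p, groups), a, n) >= f_obs - 1e-12) {
      exceed <- exceed + 1L
    }
  }
  list(pseudo_f = f_obs, p_value = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Weiszfeld spatial median
#' @noRd
spatial_median <- function(X, tol = 1e-10, maxit = 1000L) {
  if (nrow(X) == 1L) return(X[1L, ])
  m <- colMeans(X)
  for (it in seq_len(maxit)) {
    dd <- sqrt(rowSums(sweep(X, 2L, m)^2))
    dd[dd < 1e-12] <- 1e-12
    w <- 1 / dd
    m_new <- colSums(X * w) / sum(w)
    if (sum(abs(m_new - m)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the dissimilarity matrix by PCoA (keeping imaginary axes from
#' negative eigenvalues), computes each sample's distance to its group's
#' spatial median with the standard correction (squared imaginary-part
#' distances subtracted), and tests equality of mean dispersion with a
#' one-way F whose null distribution comes from permuting group labels over
#' the distances-to-median.
#'
#' @inheritParams permanova
#' @return List: `f_value`, `p_value`, `distances` (per-sample distance to
#'   group median).
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- droplevels(as.factor(groups))
  n <- nrow(d)
  stopifnot(length(groups) == n, nlevels(groups) >= 2L)
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  neg <- eig$values < -tol
  Xr <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), nrow = sum(pos))
  Xi <- if (any(neg)) {
    eig$vectors[, neg, drop = FALSE] %*%
      diag(sqrt(-eig$values[neg]), nrow = sum(neg))
  } else matrix(0, n, 1L)
  z <- numeric(n)
  for (g in levels(groups)) {
    ix <- which(groups == g)
    mr <- spatial_median(Xr[ix, , drop = FALSE])
    mi <- spatial_median(Xi[ix, , drop = FALSE])
    d2r <- rowSums(sweep(Xr[ix, , drop = FALSE], 2L, mr)^2)
    d2i <- rowSums(sweep(Xi[ix, , drop = FALSE], 2L, mi)^2)
    z[ix] <- sqrt(pmax(d2r - d2i, 0))
  }
  anova_f <- function(y, grp) {
    gm <- tapply(y, grp, mean)
    ng <- tabulate(grp)
    ss_b <- sum(ng * (gm - mean(y))^2)
    ss_w <- sum((y - gm[as.integer(grp)])^2)
    a <- nlevels(grp)
    (ss_b / (a - 1)) / (ss_w / (length(y) - a))
  }
  f_obs <- anova_f(z, groups)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (anova_f(z[sample.int(n)], groups) >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  list(f_value = f_obs, p_value = (1 + exceed) / (1 + n_perm), distances = z)
}

simper_avg <- function(counts, ix1, ix2) {
  pair_contrib <- matrix(0, nrow = ncol(counts),
                         ncol = length(ix1) * length(ix2))
  p <- 0L
  for (i in ix1) {
    for (j in ix2) {
      p <- p + 1L
      den <- sum(counts[i, ] + counts[j, ])
      pair_contrib[, p] <- abs(counts[i, ] - counts[j, ]) / den
    }
  }
  pair_contrib
}

#' Similarity percentage analysis (SIMPER) for two groups
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-taxon contributions: for each between-group sample pair, taxon i
#' contributes `|x_i - y_i| / sum(x + y)`; contributions are averaged over
#' all between-group pairs (their per-taxon sum over taxa equals the mean
#' between-group Bray-Curtis). Taxa are reported in decreasing order of
#' average contribution with the sd across pairs and the cumulative sum.
#' The permutation p-value per taxon is the fraction of group-label
#' permutations whose average contribution meets or exceeds the observed
#' one (the probability of seeing as large a contribution by chance).
#'
#' @param counts Samples x taxa abundance matrix.
#' @param groups Labels with exactly two groups (callers iterate over zone
#'   pairs).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return Data frame: taxon, average, sd, cumulative, p_value, ordered by
#'   decreasing average contribution; attribute `overall` holds the mean
#'   between-group dissimilarity.
#' @export
simper <- function(counts, groups, n_perm = 999, seed = 1L) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) {
    stop("simper takes exactly two groups per call; iterate over pairs")
  }
  n <- nrow(counts)
  ix1 <- which(groups == levels(groups)[1L])
  ix2 <- which(groups == levels(groups)[2L])
  pc <- simper_avg(counts, ix1, ix2)
  avg <- rowMeans(pc)
  sdv <- apply(pc, 1L, stats::sd)
  set.seed(seed)
  exceed <- rep(0L, ncol(counts))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    avg_p <- rowMeans(simper_avg(counts, p[seq_along(ix1)],
                                 p[seq.int(length(ix1) + 1L, n)]))
    exceed <- exceed + as.integer(avg_p >= avg - 1e-12)
  }
  ord <- order(avg, decreasing = TRUE)
  out <- data.frame(taxon = colnames(counts)[ord], average = avg[ord],
                    sd = sdv[ord], cumulative = cumsum(avg[ord]),
                    p_value = ((1 + exceed) / (1 + n_perm))[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "overall") <- sum(avg)
  out
}
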