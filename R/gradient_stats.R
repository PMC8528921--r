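#' Kruskal-Wallis rank-sum test for grouped measurements
#'
#' Omnibus nonparametric test for differences in rate or abundance
#' distributions across climatic zones (or any grouping); tie-corrected H
#' with a chi-square reference distribution on groups - 1 degrees of
#' freedom (via [stats::kruskal.test()]).
#'
#' @param values Numeric measurements.
#' @param groups Group labels (>= 2 groups).
#' @return List: `h`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  kt <- stats::kruskal.test(values, groups)
  list(h = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn post-hoc test with Benjamini-Hochberg correction
#'
#' Pairwise z statistics from pooled rank means with the usual tie
#' correction: `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t) / (12 (N - 1))` over tie groups; two-sided normal
#' p-values adjusted by the BH step-up procedure (monotone by construction).
#'
#' @inheritParams kruskal_wallis
#' @return Data frame: group1, group2, z, p_raw, p_adjusted.
#' @export
dunn_bh <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) == 0L)) stop("empty group")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ng <- table(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  z <- apply(pairs, 2L, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / ng[[pr[1L]]] + 1 / ng[[pr[2L]]]))
    if (se == 0) return(0)
    (rbar[[pr[1L]]] - rbar[[pr[2L]]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
             p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Screen predictors for collinearity and variance inflation
#'
#' Two-stage screen used before single-predictor linear models. Stage 1:
#' while any predictor pair has squared Pearson correlation above
#' `pairwise_r2_cut`, drop from the worst pair the predictor with the higher
#' mean absolute correlation to all remaining predictors. Stage 2:
#' iteratively drop the predictor with the largest variance inflation factor
#' (`1 / (1 - R^2)` from regressing it on the others) until all VIF are
#' below `vif_cut`. Constant predictors are dropped first with a warning.
#' Ties break deterministically by predictor name order.
#'
#' @param x Numeric matrix or data frame (samples x predictors) with column
#'   names; complete cases only.
#' @param pairwise_r2_cut Squared-correlation cut-off (default 0.8).
#' @param vif_cut VIF cut-off (default 5).
#' @return Character vector of retained predictor names; the exit state
#'   satisfies both criteria.
#' @export
select_predictors <- function(x, pairwise_r2_cut = 0.8, vif_cut = 5) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2L, !is.null(names(x)))
  const <- vapply(x, function(v) stats::sd(v) == 0 || is.na(stats::sd(v)),
                  logical(1))
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  keep <- sort(names(x))
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(stats::cor(x[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm^2) <= pairwise_r2_cut) break
    worst <- which(cm^2 == max(cm^2), arr.ind = TRUE)[1L, ]
    cand <- keep[worst]
    mean_abs <- vapply(cand, function(nm) mean(cm[nm, keep != nm]), numeric(1))
    drop_nm <- cand[order(-mean_abs, cand)][1L]
    keep <- setdiff(keep, drop_nm)
  }
  vif_of <- function(nm, others) {
    if (length(others) == 0L) return(1)
    r2 <- suppressWarnings(
      summary(stats::lm(x[[nm]] ~ ., data = x[, others, drop = FALSE]))
    )$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }
  repeat {
    if (length(keep) < 2L) break
    vifs <- vapply(keep, function(nm) vif_of(nm, setdiff(keep, nm)), numeric(1))
    if (max(vifs) < vif_cut) break
    drop_nm <- keep[order(-vifs, keep)][1L]
    keep <- setdiff(keep, drop_nm)
  }
  keep
}

#' Single-predictor ordinary least squares
#'
#' Fits `response ~ predictor`, returning the slope, intercept, coefficient
#' of determination, and the two-sided t-test p-value for the slope; used
#' to quantify variance in rates or gene abundances explained by one
#' environmental predictor.
#'
#' @param response,predictor Numeric vectors of equal length (n >= 3).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
fit_linear <- function(response, predictor) {
  stopifnot(length(response) == length(predictor), length(response) >= 3L)
  if (stats::sd(predictor) == 0) stop("constant predictor")
  fit <- stats::lm(response ~ predictor)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L])
}
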