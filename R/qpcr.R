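#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean quantification cycle (Cp) on log10 template
#' copies over a plasmid dilution series. Replicate Cp values are averaged on
#' the Cp scale per dilution level before regression. Amplification
#' efficiency is `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle);
#' values outside \[0.7, 1.15\] trigger a warning.
#'
#' @param standards Data frame with columns `copies` and `cp`.
#' @return A `standard_curve` list: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `cp_range` (range of level-mean Cp, for extrapolation
#'   checks).
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(all(c("copies", "cp") %in% names(standards)),
            all(standards$copies > 0), all(standards$cp > 0))
  lv <- stats::aggregate(cp ~ copies, data = standards, FUN = mean)
  if (nrow(lv) < 4L) stop("need at least 4 standard dilution levels")
  fit <- stats::lm(cp ~ log10(copies), data = lv)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("inverted standard curve: slope must be negative")
  eff <- 10^(-1 / slope) - 1
  if (eff < 0.7 || eff > 1.15) {
    warning(sprintf("amplification efficiency %.2f outside [0.70, 1.15]", eff))
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lv$cp - mean(lv$cp))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 efficiency = eff,
                 cp_range = range(lv$cp)),
            class = "standard_curve")
}

#' Quantify template copies from sample Cp values
#'
#' Inverts the standard curve on the mean of the replicate Cp values:
#' `copies_per_reaction = 10^((mean_cp - intercept) / slope)`, then scales
#' to copies per gram of soil through the extraction chain:
#' `copies_per_g = copies_per_reaction * (elution_volume / template_volume)
#' / extracted_mass_g`. Cp values outside the standard range are flagged as
#' extrapolated with a warning.
#'
#' @param cp Replicate Cp values for one sample (e.g. a triplicate).
#' @param curve A `standard_curve`.
#' @param template_volume_ul Template volume per reaction (uL).
#' @param elution_volume_ul DNA elution volume (uL).
#' @param extracted_mass_g Soil mass extracted (g, default 0.25).
#' @return List: `copies_per_reaction`, `copies_per_g`, `extrapolated`.
#' @export
quantify_sample <- function(cp, curve, template_volume_ul = 2,
                            elution_volume_ul = 100, extracted_mass_g = 0.25) {
  stopifnot(inherits(curve, "standard_curve"), length(cp) >= 1L,
            template_volume_ul > 0, elution_volume_ul > 0,
            extracted_mass_g > 0)
  m <- mean(cp)
  extrapolated <- m < curve$cp_range[1L] || m > curve$cp_range[2L]
  if (extrapolated) {
    warning(sprintf("mean Cp %.2f outside standard range [%.2f, %.2f]; extrapolating",
                    m, curve$cp_range[1L], curve$cp_range[2L]))
  }
  per_rxn <- 10^((m - curve$intercept) / curve$slope)
  per_g <- per_rxn * (elution_volume_ul / template_volume_ul) / extracted_mass_g
  list(copies_per_reaction = per_rxn, copies_per_g = per_g,
       extrapolated = extrapolated)
}
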