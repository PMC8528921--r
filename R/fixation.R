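#' Convert scintillation counts to fixed carbon
#'
#' `nmol C = (dpm / 2.22e6) / specific_activity * 1e3`: DPM to microcuries
#' (2.22e6 DPM = 1 uCi), to micromoles via the stock's specific activity
#' (uCi per umol), to nanomoles. Counting-efficiency correction is assumed
#' applied upstream; inputs are DPM.
#'
#' @param dpm Disintegrations per minute (>= 0).
#' @param specific_activity Specific activity of the labelled stock,
#'   uCi per umol (> 0; the conventional scale for NaH14CO3 stocks).
#' @return Fixed carbon in nmol.
#' @export
dpm_to_nmol_c <- function(dpm, specific_activity = 53.1) {
  if (any(specific_activity <= 0)) stop("specific_activity must be > 0")
  if (any(dpm < 0)) stop("dpm must be >= 0")
  (dpm / 2.22e6) / specific_activity * 1e3
}

#' Net carbon-fixation rate from a live / heat-killed pair
#'
#' Subtracts the paired heat-killed control (which carries the abiotic and
#' background signal) and normalizes to soil mass and incubation time:
#' `rate = (nmol_live - nmol_killed) / soil_mass_g / incubation_h`.
#' Negative rates are floored at 0 and flagged. Pairs must match on
#' `pool_id`; DPM replicates are averaged before conversion.
#'
#' @param live,killed One-or-more-row data frames for the same pool with
#'   columns `pool_id`, `dpm`, `soil_mass_g`, `incubation_h`,
#'   `specific_activity`.
#' @return List: `rate_nmol_per_g_h`, `flagged`.
#' @export
net_fixation <- function(live, killed) {
  if (!all(live$pool_id[1L] == c(live$pool_id, killed$pool_id))) {
    stop("live and heat-killed assays must come from the same pool")
  }
  sa <- live$specific_activity[1L]
  nmol_live <- dpm_to_nmol_c(mean(live$dpm), sa)
  nmol_killed <- dpm_to_nmol_c(mean(killed$dpm), sa)
  rate <- (nmol_live - nmol_killed) / live$soil_mass_g[1L] / live$incubation_h[1L]
  list(rate_nmol_per_g_h = max(rate, 0), flagged = rate < 0)
}

#' Partition net fixation rates into three processes
#'
#' Given net (heat-killed-corrected) rates under the three live treatments,
#' dark assimilation is the dark rate itself; photosynthetic fixation is the
#' additional CO2 fixed under light (`light - dark`); hydrogenotrophic
#' fixation is the additional CO2 fixed under dark H2-enriched conditions
#' (`h2 - dark`). Negative components are floored at 0 and flagged.
#'
#' @param dark_rate,light_rate,h2_rate Net rates (nmol C per g per h).
#' @param pool_id Optional pool label carried through.
#' @return Data frame: pool_id, dark_assimilation, photosynthetic,
#'   hydrogenotrophic, flagged (any component floored).
#' @export
partition_processes <- function(dark_rate, light_rate, h2_rate,
                                pool_id = NA_character_) {
  if (any(is.na(c(dark_rate, light_rate, h2_rate)))) {
    stop("all three treatment rates (dark, light, +H2) are required")
  }
  photo <- light_rate - dark_rate
  hydro <- h2_rate - dark_rate
  flagged <- photo < 0 || hydro < 0
  data.frame(pool_id = pool_id,
             dark_assimilation = dark_rate,
             photosynthetic = max(photo, 0),
             hydrogenotrophic = max(hydro, 0),
             flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Full fixation chain for one pool's assay table
#'
#' Convenience wrapper: splits an assay table (as produced by
#' [simulate_fixation()]) by treatment, computes net rates against the
#' heat-killed control, and partitions them.
#'
#' @param assay Data frame with columns `pool_id`, `treatment`
#'   (`dark`, `light`, `dark_plus_H2`, `heat_killed`), `replicate`, `dpm`,
#'   `soil_mass_g`, `incubation_h`, `specific_activity`.
#' @return Output of [partition_processes()].
#' @export
fixation_rates <- function(assay) {
  need <- c("dark", "light", "dark_plus_H2", "heat_killed")
  missing <- setdiff(need, unique(assay$treatment))
  if (length(missing) > 0L) {
    stop("assay missing treatment(s): ", paste(missing, collapse = ", "))
  }
  killed <- assay[assay$treatment == "heat_killed", , drop = FALSE]
  net <- function(tr) {
    net_fixation(assay[assay$treatment == tr, , drop = FALSE], killed)$rate_nmol_per_g_h
  }
  partition_processes(net("dark"), net("light"), net("dark_plus_H2"),
                      pool_id = assay$pool_id[1L])
}
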