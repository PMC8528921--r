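#' Simulate a sealed-vial headspace gas time series
#'
#' First-order draw-down towards an equilibrium floor,
#' `C(t) = Ceq + (C0 - Ceq) * exp(-k t) + eps`, emulating microcosm H2
#' uptake monitored by gas chromatography from a ~10 ppmv amended headspace.
#' Noise is additive Gaussian (`noise_sd_ppmv`) by default, or proportional
#' (`noise_sd_ppmv` read as a fraction of the signal) for multiplicative
#' measurement error.
#'
#' @param k_per_h True first-order rate constant (1/h, >= 0).
#' @param c0_ppmv Starting mixing ratio (ppmv).
#' @param ceq_ppmv Equilibrium floor (ppmv, >= 0).
#' @param times_h Sampling times (h, >= 0).
#' @param noise_sd_ppmv Noise sd (ppmv, or fraction if proportional).
#' @param noise_type `"additive"` or `"proportional"`.
#' @param seed Integer seed (ignored when noise is 0).
#' @param sample_id,condition,is_control,zone,stratum Series labels.
#' @param vial_volume_l,soil_mass_g,temperature_k,pressure_pa Vial geometry
#'   and lab conditions (defaults: 0.120 L, 5 g, 298.15 K, 101325 Pa).
#' @return A `gas_series` object (list).
#' @export
simulate_gas_series <- function(k_per_h, c0_ppmv, ceq_ppmv, times_h,
                                noise_sd_ppmv = 0,
                                noise_type = c("additive", "proportional"),
                                seed = 1L, sample_id = "S1",
                                condition = "wet", is_control = "live",
                                zone = "arid", stratum = "topsoil",
                                vial_volume_l = 0.120, soil_mass_g = 5,
                                temperature_k = 298.15, pressure_pa = 101325) {
  noise_type <- match.arg(noise_type)
  if (any(times_h < 0)) stop("negative times not allowed")
  stopifnot(k_per_h >= 0, ceq_ppmv >= 0)
  mu <- ceq_ppmv + (c0_ppmv - ceq_ppmv) * exp(-k_per_h * times_h)
  if (noise_sd_ppmv > 0) {
    set.seed(seed)
    eps <- if (noise_type == "additive") {
      stats::rnorm(length(mu), 0, noise_sd_ppmv)
    } else {
      mu * stats::rnorm(length(mu), 0, noise_sd_ppmv)
    }
    mu <- pmax(mu + eps, 0)
  }
  gas_series(sample_id = sample_id, times_h = times_h, ppmv = mu,
             vial_volume_l = vial_volume_l, soil_mass_g = soil_mass_g,
             temperature_k = temperature_k, pressure_pa = pressure_pa,
             condition = condition, is_control = is_control,
             zone = zone, stratum = stratum)
}

#' Construct a gas series object
#'
#' @inheritParams simulate_gas_series
#' @param ppmv Measured mixing ratios (ppmv, >= 0).
#' @return A `gas_series` object.
#' @export
gas_series <- function(sample_id, times_h, ppmv,
                       vial_volume_l = 0.120, soil_mass_g = 5,
                       temperature_k = 298.15, pressure_pa = 101325,
                       condition = "dry", is_control = "live",
                       zone = NA_character_, stratum = NA_character_) {
  stopifnot(length(times_h) == length(ppmv), all(ppmv >= 0),
            vial_volume_l > 0, soil_mass_g > 0, !is.unsorted(times_h))
  structure(list(sample_id = sample_id, times_h = as.numeric(times_h),
                 ppmv = as.numeric(ppmv), vial_volume_l = vial_volume_l,
                 soil_mass_g = soil_mass_g, temperature_k = temperature_k,
                 pressure_pa = pressure_pa, condition = condition,
                 is_control = is_control, zone = zone, stratum = stratum),
            class = "gas_series")
}

#' Simulate a qPCR run with a plasmid standard dilution series
#'
#' Quantification cycles follow the log-linear standard model
#' `Cp = intercept + slope * log10(copies) + eps`. Standards are generated
#' at the supplied copy numbers in duplicate; samples in triplicate.
#'
#' @param copies_per_reaction Named numeric vector of true sample template
#'   copies per reaction (names are sample ids).
#' @param slope,intercept Standard-curve parameters (slope in Cp per log10
#'   copies, negative for a valid run).
#' @param cp_noise_sd Gaussian Cp noise sd.
#' @param standard_copies Copy numbers of the dilution series (default
#'   ten-fold from 1e3 to 1e8).
#' @param n_standard_reps,n_sample_reps Replication (defaults 2 and 3).
#' @param seed Integer seed.
#' @return List with `standards` (copies, cp) and `samples`
#'   (sample_id, replicate, cp).
#' @export
simulate_qpcr <- function(copies_per_reaction, slope = -3.3219, intercept = 38,
                          cp_noise_sd = 0, standard_copies = 10^(3:8),
                          n_standard_reps = 2L, n_sample_reps = 3L, seed = 1L) {
  stopifnot(all(copies_per_reaction > 0), all(standard_copies > 0))
  set.seed(seed)
  std <- data.frame(
    copies = rep(standard_copies, each = n_standard_reps),
    cp = intercept + slope * log10(rep(standard_copies, each = n_standard_reps))
  )
  std$cp <- std$cp + stats::rnorm(nrow(std), 0, cp_noise_sd)
  ids <- names(copies_per_reaction)
  if (is.null(ids)) ids <- sprintf("S%d", seq_along(copies_per_reaction))
  smp <- data.frame(
    sample_id = rep(ids, each = n_sample_reps),
    replicate = rep(seq_len(n_sample_reps), length(ids)),
    cp = intercept + slope * log10(rep(unname(copies_per_reaction),
                                       each = n_sample_reps))
  )
  smp$cp <- smp$cp + stats::rnorm(nrow(smp), 0, cp_noise_sd)
  list(standards = std, samples = smp)
}

#' Simulate a radiolabel carbon-fixation assay
#'
#' Generates scintillation counts (DPM) for the four-treatment design: dark,
#' light, dark + H2, and a paired heat-killed control. The generative model
#' is additive: `DPM = background + (dark + photo * 1[light] +
#' hydro * 1[+H2]) * mass * hours * dpm_per_nmol + eps`, where `dpm_per_nmol`
#' converts fixed carbon to counts at the stock's specific activity. The
#' heat-killed control carries only the background, so subtracting it removes
#' any additive abiotic constant.
#'
#' @param rates Named list/vector with elements `dark`, `photo`, `hydro`
#'   (true rates, nmol C per g per h).
#' @param pool_id Pool label (zone x stratum).
#' @param killed_background_dpm Abiotic/background DPM common to all vials.
#' @param specific_activity Stock specific activity, uCi per umol
#'   (default 53.1).
#' @param incubation_h Incubation time (default 96 h).
#' @param soil_mass_g Soil mass per vial (default 0.25 g).
#' @param dpm_noise_sd Gaussian DPM noise sd.
#' @param n_reps Technical replicates per treatment (default 3).
#' @param seed Integer seed.
#' @return Data frame: pool_id, treatment, replicate, dpm, soil_mass_g,
#'   incubation_h, specific_activity.
#' @export
simulate_fixation <- function(rates, pool_id = "arid.biocrust",
                              killed_background_dpm = 500,
                              specific_activity = 53.1, incubation_h = 96,
                              soil_mass_g = 0.25, dpm_noise_sd = 0,
                              n_reps = 3L, seed = 1L) {
  stopifnot(all(c("dark", "photo", "hydro") %in% names(rates)))
  set.seed(seed)
  dpm_per_nmol <- specific_activity * 2.22e6 / 1e3  # uCi/umol * DPM/uCi * umol/nmol
  tr_rate <- c(dark = rates[["dark"]],
               light = rates[["dark"]] + rates[["photo"]],
               dark_plus_H2 = rates[["dark"]] + rates[["hydro"]],
               heat_killed = 0)
  out <- do.call(rbind, lapply(names(tr_rate), function(tr) {
    mu <- killed_background_dpm +
      tr_rate[[tr]] * soil_mass_g * incubation_h * dpm_per_nmol
    data.frame(pool_id = pool_id, treatment = tr, replicate = seq_len(n_reps),
               dpm = pmax(mu + stats::rnorm(n_reps, 0, dpm_noise_sd), 0),
               soil_mass_g = soil_mass_g, incubation_h = incubation_h,
               specific_activity = specific_activity, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a gradient-structured OTU count table
#'
#' Taxon log-abundance profiles are shared across samples, shifted per zone
#' by `zone_effect_size` times a taxon-by-zone standard-normal deviation;
#' per-sample counts are multinomial at the stated sequencing depth. At
#' `zone_effect_size = 0` all zones share one composition (the null).
#'
#' @param n_zones Number of zones (default 4).
#' @param samples_per_zone Samples per zone.
#' @param n_taxa Number of taxa.
#' @param zone_effect_size Scale of the per-zone log-abundance shift.
#' @param depth Reads per sample.
#' @param base_log_sd Sd of baseline taxon log-abundances (default 1.5).
#' @param seed Integer seed.
#' @return List with `counts` (samples x taxa integer matrix) and `zone`
#'   (factor of zone labels).
#' @export
simulate_otu_gradient <- function(n_zones = 4, samples_per_zone = 6,
                                  n_taxa = 100, zone_effect_size = 1,
                                  depth = 25000, base_log_sd = 1.5, seed = 1L) {
  stopifnot(n_zones >= 1, samples_per_zone >= 1, n_taxa >= 2, depth > 0)
  set.seed(seed)
  base <- stats::rnorm(n_taxa, 0, base_log_sd)
  zones <- paste0("zone", seq_len(n_zones))
  counts <- matrix(0L, nrow = n_zones * samples_per_zone, ncol = n_taxa,
                   dimnames = list(
                     paste0(rep(zones, each = samples_per_zone), ".s",
                            rep(seq_len(samples_per_zone), n_zones)),
                     sprintf("taxon%03d", seq_len(n_taxa))))
  row <- 0L
  for (z in seq_len(n_zones)) {
    shift <- zone_effect_size * stats::rnorm(n_taxa)
    p <- exp(base + shift)
    p <- p / sum(p)
    for (s in seq_len(samples_per_zone)) {
      row <- row + 1L
      counts[row, ] <- stats::rmultinom(1, depth, p)[, 1L]
    }
  }
  list(counts = counts,
       zone = factor(rep(zones, each = samples_per_zone), levels = zones))
}
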