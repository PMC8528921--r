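#' Run the analysis pipeline end-to-end over a run configuration
#'
#' Chains the stages — marker-gene profiling, qPCR quantification, gas
#' kinetics, carbon-fixation partitioning, diversity, and gradient
#' statistics — over whichever inputs the configuration provides. Stages
#' communicate only through documented TSV schemas, so any stage can be
#' re-run from files alone; outputs land in `out_dir` together with a JSON
#' manifest (tables, seeds, package version) and a summary of headline
#' quantities (per-process community percentages, zone fold-changes,
#' fixation partitions).
#'
#' @param config A list, or path to a YAML file, with elements:
#'   `out_dir`; `seeds` (named: `rarefy`, `permutation`); `options`
#'   (`process_rule` = "sum"/"max", `chao1_variant`, `rarefy_depth`);
#'   `inputs`, a named list of file paths: `hits` (named list, one 13-column
#'   hit file per sample), `registry`, `libraries`, `qpcr_standards`,
#'   `qpcr_samples`, `gas_series` (long TSV: sample_id, time_h, ppmv),
#'   `vials` (sample_id, vial_volume_l, soil_mass_g, temperature_k,
#'   pressure_pa, condition, is_control, zone, stratum), `fixation` (DPM
#'   table), `otu_table` (taxa rows x sample columns, first column
#'   taxon_id), `sample_groups` (sample_id, zone).
#' @param stages Which stages to run; defaults to every stage whose inputs
#'   are present. A requested stage with missing inputs is an error naming
#'   the stage.
#' @return Invisibly, a list with per-stage result tables and the summary.
#' @export
run_pipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  inputs <- config$inputs
  opts <- config$options
  seeds <- config$seeds
  if (is.null(seeds)) seeds <- list()
  if (is.null(seeds$rarefy)) seeds$rarefy <- 1L
  if (is.null(seeds$permutation)) seeds$permutation <- 1L
  rule <- if (is.null(opts$process_rule)) "sum" else opts$process_rule
  chao_variant <- if (is.null(opts$chao1_variant)) "bias_corrected" else opts$chao1_variant

  for (nm in setdiff(names(inputs), c("hits"))) {
    if (is.character(inputs[[nm]]) && !file.exists(inputs[[nm]])) {
      stop(sprintf("input '%s' does not exist: %s", nm, inputs[[nm]]))
    }
  }
  available <- c(
    profile = !is.null(inputs$hits) && !is.null(inputs$libraries),
    qpcr = !is.null(inputs$qpcr_standards) && !is.null(inputs$qpcr_samples),
    rates = !is.null(inputs$gas_series) && !is.null(inputs$vials),
    fixation = !is.null(inputs$fixation),
    diversity = !is.null(inputs$otu_table) && !is.null(inputs$sample_groups),
    stats = !is.null(inputs$gas_series) && !is.null(inputs$vials)
  )
  if (is.null(stages)) {
    stages <- names(available)[available]
  } else {
    bad <- stages[!available[stages]]
    if (length(bad) > 0L) {
      stop("missing required input for requested stage(s): ",
           paste(bad, collapse = ", "))
    }
  }
  skipped <- setdiff(names(available), stages)
  if (length(skipped) > 0L) {
    message("stages skipped (inputs absent or not requested): ",
            paste(skipped, collapse = ", "))
  }
  registry <- if (!is.null(inputs$registry)) {
    read_marker_registry(inputs$registry)
  } else default_registry()

  tables <- list()
  summary <- list(stages = as.list(stages))
  results <- list()

  if ("profile" %in% stages) {
    libs <- read_tidy_table(inputs$libraries)
    prof <- do.call(rbind, lapply(names(inputs$hits), function(sid) {
      hits <- read_hit_table(inputs$hits[[sid]], sid, registry = registry)
      profile_sample(hits, registry, libs[libs$sample_id == sid, , drop = FALSE])
    }))
    prof <- prof[order(prof$sample_id, prof$family_id), , drop = FALSE]
    proc <- aggregate_process(prof,
                              stats::setNames(registry$process, registry$family_id),
                              rule = rule)
    tables$profile <- prof
    tables$process <- proc
    results$profile <- prof
    results$process <- proc
    summary$process_rule <- rule
    summary$mean_process_percent <- stats::setNames(
      as.list(round(tapply(proc$process_percent, proc$process, mean), 3)),
      names(tapply(proc$process_percent, proc$process, mean)))
  }

  if ("qpcr" %in% stages) {
    std <- read_tidy_table(inputs$qpcr_standards)
    smp <- read_tidy_table(inputs$qpcr_samples)
    curve <- fit_standard_curve(std)
    conv <- inputs$qpcr_conversion
    if (is.null(conv)) conv <- list()
    qres <- do.call(rbind, lapply(split(smp, smp$sample_id), function(s) {
      q <- quantify_sample(
        s$cp, curve,
        template_volume_ul = conv$template_volume_ul %||% 2,
        elution_volume_ul = conv$elution_volume_ul %||% 100,
        extracted_mass_g = conv$extracted_mass_g %||% 0.25)
      data.frame(sample_id = s$sample_id[1L],
                 copies_per_reaction = q$copies_per_reaction,
                 copies_per_g = q$copies_per_g,
                 extrapolated = q$extrapolated, stringsAsFactors = FALSE)
    }))
    qres <- qres[order(qres$sample_id), , drop = FALSE]
    rownames(qres) <- NULL
    tables$qpcr <- qres
    results$qpcr <- qres
    summary$qpcr_efficiency <- round(curve$efficiency, 4)
  }

  if ("rates" %in% stages || "stats" %in% stages) {
    series_tab <- read_tidy_table(inputs$gas_series)
    vials <- read_tidy_table(inputs$vials)
    fits <- list()
    rate_rows <- list()
    blank_fits <- list()
    for (sid in unique(series_tab$sample_id)) {
      v <- vials[vials$sample_id == sid, , drop = FALSE]
      s <- series_tab[series_tab$sample_id == sid, , drop = FALSE]
      gs <- gas_series(sid, s$time_h, s$ppmv,
                       vial_volume_l = v$vial_volume_l, soil_mass_g = v$soil_mass_g,
                       temperature_k = v$temperature_k, pressure_pa = v$pressure_pa,
                       condition = v$condition, is_control = v$is_control,
                       zone = v$zone, stratum = v$stratum)
      ft <- fit_uptake(gs)
      fits[[sid]] <- list(series = gs, fit = ft)
      if (v$is_control == "blank") blank_fits[[v$condition]] <- ft
    }
    copies <- if (!is.null(results$qpcr)) {
      stats::setNames(results$qpcr$copies_per_g, results$qpcr$sample_id)
    } else NULL
    for (sid in names(fits)) {
      gs <- fits[[sid]]$series
      if (gs$is_control != "live") next
      br <- bulk_rate(fits[[sid]]$fit, gs, blank_fits[[gs$condition]])
      # gas series may be suffixed with the condition ("<sample>.wet");
      # fall back to the base sample id when matching qPCR copies
      qid <- if (!is.null(copies) && sid %in% names(copies)) sid else {
        sub(paste0("[.]", gs$condition, "$"), "", sid)
      }
      csr <- if (!is.null(copies) && qid %in% names(copies) &&
                 !is.na(copies[qid])) {
        cell_specific_rate(br$rate_nmol_per_g_h, copies[[qid]])
      } else NA_real_
      rate_rows[[sid]] <- data.frame(
        sample_id = sid, condition = gs$condition, zone = gs$zone,
        stratum = gs$stratum,
        k_per_h = fits[[sid]]$fit$k_per_h, model = fits[[sid]]$fit$model,
        bulk_rate_nmol_per_g_h = br$rate_nmol_per_g_h,
        cell_specific_amol_per_copy_h = csr,
        flagged = br$flagged, stringsAsFactors = FALSE)
    }
    rates_tab <- do.call(rbind, rate_rows)
    rates_tab <- rates_tab[order(rates_tab$sample_id, rates_tab$condition), ,
                           drop = FALSE]
    rownames(rates_tab) <- NULL
    fit_tab <- do.call(rbind, lapply(names(fits), function(sid) {
      ft <- fits[[sid]]$fit
      data.frame(sample_id = sid, k_per_h = ft$k_per_h, c0_ppmv = ft$c0_ppmv,
                 ceq_ppmv = ft$ceq_ppmv, r_squared = ft$r_squared,
                 model = ft$model, flag = ft$flag, stringsAsFactors = FALSE)
    }))
    fit_tab <- fit_tab[order(fit_tab$sample_id), , drop = FALSE]
    rownames(fit_tab) <- NULL
    tables$uptake_fits <- fit_tab
    tables$rates <- rates_tab
    results$rates <- rates_tab
    zones <- unique(vials$zone[vials$is_control == "live"])
    zones <- zones[!is.na(zones)]
    use <- rates_tab[!is.na(rates_tab$cell_specific_amol_per_copy_h), ,
                     drop = FALSE]
    if ("wet" %in% use$condition) use <- use[use$condition == "wet", , drop = FALSE]
    if (length(zones) >= 2L && nrow(use) > 0L &&
        all(c(zones[1L], zones[length(zones)]) %in% use$zone)) {
      fc <- zone_fold_change(
        data.frame(sample_id = use$sample_id, zone = use$zone,
                   rate = use$cell_specific_amol_per_copy_h),
        from_zone = zones[1L], to_zone = zones[length(zones)])
      summary$cell_specific_fold_change <- round(fc$fold_of_means, 3)
    }
    # paired hydration stimulation: same sample under wet vs dry; samples
    # whose dry rate fell below the blank (floored at 0) are detection-
    # limited and excluded from the ratio
    both <- rates_tab[rates_tab$condition %in% c("wet", "dry"), , drop = FALSE]
    if (all(c("wet", "dry") %in% both$condition)) {
      base_id <- sub("[.](wet|dry)$", "", both$sample_id)
      zero_dry <- unique(base_id[both$condition == "dry" &
                                   both$bulk_rate_nmol_per_g_h <= 0])
      keep <- !(base_id %in% zero_dry)
      wd <- try(zone_fold_change(
        data.frame(sample_id = base_id[keep], zone = both$condition[keep],
                   rate = both$bulk_rate_nmol_per_g_h[keep]),
        from_zone = "dry", to_zone = "wet", paired = TRUE), silent = TRUE)
      if (!inherits(wd, "try-error")) {
        # mean-of-ratios follows each sample's own stimulation but is
        # sensitive to near-detection-limit dry rates; the ratio of means
        # is the robust companion
        summary$wet_dry_fold <- round(wd$fold_of_means, 3)
        summary$wet_dry_mean_of_ratios <- round(wd$mean_of_ratios, 3)
        summary$wet_dry_n_pairs <- sum(keep) / 2
      }
    }
  }

  if ("fixation" %in% stages) {
    dpm <- read_tidy_table(inputs$fixation)
    fx <- do.call(rbind, lapply(split(dpm, dpm$pool_id), fixation_rates))
    fx <- fx[order(fx$pool_id), , drop = FALSE]
    rownames(fx) <- NULL
    tables$fixation <- fx
    results$fixation <- fx
    summary$fixation_partition <- lapply(split(fx, fx$pool_id), function(r) {
      list(dark = round(r$dark_assimilation, 5),
           photosynthetic = round(r$photosynthetic, 5),
           hydrogenotrophic = round(r$hydrogenotrophic, 5))
    })
  }

  if ("diversity" %in% stages) {
    otu_raw <- read_tidy_table(inputs$otu_table)
    counts <- t(as.matrix(otu_raw[, -1L, drop = FALSE]))
    colnames(counts) <- otu_raw[[1L]]
    storage.mode(counts) <- "integer"
    grp_tab <- read_tidy_table(inputs$sample_groups)
    if (!is.null(opts$rarefy_depth)) {
      counts <- rarefy(counts, opts$rarefy_depth, seed = seeds$rarefy)
    }
    grp <- grp_tab$zone[match(rownames(counts), grp_tab$sample_id)]
    alpha <- data.frame(
      sample_id = rownames(counts), zone = grp,
      observed = apply(counts, 1L, function(x) sum(x > 0)),
      chao1 = apply(counts, 1L, chao1, variant = chao_variant),
      stringsAsFactors = FALSE)
    d <- bray_curtis(counts)
    ord <- pcoa(d, k = 2L)
    pa <- permanova(d, grp, n_perm = 999, seed = seeds$permutation)
    pd <- permdisp(d, grp, n_perm = 999, seed = seeds$permutation)
    test_tab <- data.frame(
      test = c("PERMANOVA", "PERMDISP"),
      statistic = c(pa$pseudo_f, pd$f_value),
      p_value = c(pa$p_value, pd$p_value), stringsAsFactors = FALSE)
    tables$alpha_diversity <- alpha
    tables$dissimilarity <- data.frame(sample_id = rownames(d),
                                       as.data.frame(d))
    tables$ordination <- data.frame(sample_id = rownames(ord$points),
                                    as.data.frame(ord$points))
    tables$diversity_tests <- test_tab
    results$alpha <- alpha
    results$diversity_tests <- test_tab
    zl <- unique(grp)
    if (length(zl) >= 2L) {
      pair <- grp %in% c(zl[1L], zl[length(zl)])
      tables$simper <- simper(counts[pair, , drop = FALSE], grp[pair],
                              n_perm = 999, seed = seeds$permutation)
    }
    summary$permanova_p <- pa$p_value
  }

  if ("stats" %in% stages && !is.null(results$rates)) {
    use <- results$rates
    if ("wet" %in% use$condition) use <- use[use$condition == "wet", , drop = FALSE]
    val <- if (all(is.na(use$cell_specific_amol_per_copy_h))) {
      use$bulk_rate_nmol_per_g_h
    } else use$cell_specific_amol_per_copy_h
    ok <- !is.na(val) & !is.na(use$zone)
    if (length(unique(use$zone[ok])) >= 2L) {
      kw <- kruskal_wallis(val[ok], use$zone[ok])
      dn <- dunn_bh(val[ok], use$zone[ok])
      tables$kruskal_wallis <- data.frame(test = "Kruskal-Wallis", h = kw$h,
                                          df = kw$df, p_value = kw$p_value)
      tables$dunn <- dn
      results$kruskal_wallis <- kw
      summary$kruskal_wallis_p <- kw$p_value
    }
  }

  manifest <- write_tidy_results(tables, config$out_dir, seeds = seeds)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$summary <- summary
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
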