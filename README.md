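# desertprod

Quantifying chemosynthetic and photosynthetic primary production in desert
soil microbiomes along aridity gradients.

Desert soils carry diverse aerobic bacteria with almost no plant carbon.
Two strategies sustain them: oxygenic photosynthesis (Cyanobacteria,
biocrusts, active only when wet) and atmospheric-trace-gas chemosynthesis —
oxidation of atmospheric H₂ (0.53 ppmv) through high-affinity group 1h/1l
[NiFe]-hydrogenases, coupled in some lineages to CO₂ fixation through
chemosynthetic RuBisCO types IA/IE. `desertprod` is a tested, reusable
implementation of the full computational chain used to measure both
strategies, aimed at microbial ecologists working with metagenomic marker
profiling and trace-gas biogeochemistry:

* **Marker-gene community profiling.** BLAST-style read hits are filtered
  with gene-specific identity thresholds and >80% query coverage,
  converted to RPKM, and normalized to the mean RPKM of 14 universal
  single-copy ribosomal genes, giving the percentage of community members
  encoding each gene: `pct = 100 · RPKM_gene / mean(RPKM_ribosomal)`,
  assuming one copy per genome. MAG prevalence is reported raw and
  completeness-adjusted (`100 · n⁺ / Σ(completeness/100)`).
* **H₂ uptake kinetics.** Sealed-vial headspace series are fitted with a
  first-order draw-down to a free floor, `C(t) = Ceq + (C0−Ceq)e^(−kt)`;
  initial rates convert through the ideal gas law to bulk rates
  (nmol g⁻¹ h⁻¹) and, normalized to qPCR-derived 16S copies, to
  cell-specific rates (amol copy⁻¹ h⁻¹).
* **qPCR quantification** from a plasmid standard curve (OLS of mean Cp on
  log₁₀ copies; efficiency `10^(−1/slope) − 1`).
* **¹⁴C fixation partitioning** of scintillation counts into dark,
  photosynthetic (light − dark), and hydrogenotrophic (+H₂ − dark)
  components, heat-killed-corrected.
* **Community ecology statistics**, implemented from first principles:
  rarefaction, Chao1, Bray–Curtis, PCoA, PERMANOVA, PERMDISP, SIMPER, plus
  Kruskal–Wallis with Dunn/BH post hoc and collinearity/VIF predictor
  screening.
* **A seeded synthetic-data generator** producing every input with known
  ground truth (communities with known gene complements, gas draw-downs,
  qPCR plates, fixation assays, gradient-structured OTU tables), so every
  estimator is validated by parameter recovery.

## Worked example

```r
library(desertprod)
reg <- default_registry()

# a 200-genome community where half the genomes encode the group 1l
# high-affinity hydrogenase, sequenced to 1e6 reads
comm <- simulate_community(200, c(NiFe_group1l = 0.5, CoxL = 0.3), seed = 7)
ht <- simulate_hit_tables(comm, 1e6, registry = reg, seed = 8)
prof <- profile_sample(ht$hits, reg, ht$library)
subset(prof, family_id %in% c("NiFe_group1l", "CoxL"))
#>    sample_id    family_id read_count     rpkm community_percent capped
#> 9         S1         CoxL        249 105.0633          31.29046  FALSE
#> 28        S1 NiFe_group1l        293 165.5367          49.30095  FALSE
```

The estimator recovers the generating carriage (50% and 30%) within
counting noise: 293 retained reads over a 1.77 kb reference in a 10⁶-read
library give RPKM 165.5, against a single-copy ribosomal baseline of
~336 RPKM.

```r
# sealed-vial H2 draw-down: 10 ppmv headspace consumed towards a
# sub-atmospheric floor at k = 0.2 /h, sampled every 2 h with 2% noise
s <- simulate_gas_series(0.2, 10, 0.5, seq(0, 24, 2), noise_sd_ppmv = 0.02,
                         noise_type = "proportional", seed = 3)
fit <- fit_uptake(s)
unlist(fit[c("k_per_h", "ceq_ppmv", "model")])
#>             k_per_h            ceq_ppmv               model
#> "0.196311395597489" "0.481597776575457" "exponential_floor"

rate <- bulk_rate(fit, s)$rate_nmol_per_g_h
round(c(bulk_nmol_g_h = rate,
        cell_specific = cell_specific_rate(rate, copies_per_g = 1e9)), 3)
#> bulk_nmol_g_h cell_specific
#>           1.8           1.8
```

The fitted rate constant (0.196 h⁻¹ vs true 0.2) and floor (0.48 vs 0.5
ppmv) convert to a bulk uptake of 1.8 nmol H₂ g⁻¹ h⁻¹ for the 5 g / 120 mL
vial, and to 1.8 amol per 16S copy per hour at 10⁹ copies g⁻¹.

## The analysis workflow

`analysis/` contains the numbered study scripts, each a thin driver over
the package:

1. `01_simulate_data.R` — generate the synthetic aridity-gradient dataset
   (4 zones × 6 topsoil samples) under `scratch/synthetic/`.
2. `02_profile_metagenomes.R` — marker-gene community percentages by zone.
3. `03_gas_kinetics.R` — uptake fits, bulk and cell-specific rates, zone
   fold change and wet/dry stimulation.
4. `04_carbon_fixation.R` — fixation partitioning per zone pool.
5. `05_diversity.R` — Chao1, Bray–Curtis/PCoA, PERMANOVA/PERMDISP, SIMPER.
6. `06_gradient_stats.R` — Kruskal–Wallis + Dunn/BH, predictor screening,
   linear models.

Run them in order from the repository root (`Rscript analysis/01_...`);
summary tables land under `results/analysis/`. `run_pipeline()` exposes the
same stages programmatically over a YAML or list configuration.

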