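---
title: "Methods: profiling chemosynthetic and photosynthetic primary production along desert aridity gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desert primary production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desertprod)
```

## Scientific setting

Desert soils host abundant aerobic bacteria despite negligible plant carbon
inputs. Two energy strategies explain this: oxygenic photosynthesis by
Cyanobacteria (largely confined to biocrusts and active only when wet) and
trace-gas chemosynthesis — oxidation of atmospheric H₂ (0.53 ppmv) through
high-affinity group 1h/1l [NiFe]-hydrogenases, in some lineages coupled to
CO₂ fixation through chemosynthetic RuBisCO lineages (types IA/IE).
`desertprod` implements the complete computational chain used to quantify
both strategies along an aridity gradient: marker-gene community profiling
from metagenomic short-read hits, H₂ uptake kinetics from sealed-vial
headspace series, absolute 16S quantification by qPCR, ¹⁴C fixation
partitioning, and the community-ecology statistics that frame them. A
seeded synthetic-data generator produces every input with known ground
truth, so each estimator is validated by parameter recovery rather than by
re-downloading the original sequencing data.

## The community-fraction estimator

The core statistic converts filtered read counts into "percent of community
members encoding gene X". For a marker family with reference length $L$
(bp) and retained read count $n$ in a library of $N$ reads,

$$\mathrm{RPKM} = \frac{n}{(L/1000)\,(N/10^6)}.$$

Fourteen universal single-copy ribosomal genes are profiled the same way;
their mean RPKM $\bar B$ (zeros included) is the abundance of a gene
carried exactly once by 100% of community members. The estimate is

$$\widehat{\mathrm{pct}} = 100 \cdot \mathrm{RPKM}_\text{gene} / \bar B,$$

assuming one copy per genome. Values above 100% are reported with a
`capped` flag, never truncated — they indicate multi-copy carriage (a
constructed two-copy community doubles the estimate, which the test suite
asserts) or counting noise. Process-level summaries ("at least one gene of
the process") default to the capped sum over member families; a `max` rule
is selectable, and the rule used is recorded in the output manifest,
because the union of carriers is not identifiable from read counts alone.

**Filtering.** Metabolic hits are retained when query coverage is strictly
above 80% and the amino-acid identity is at or above the family threshold
(60% for NxrA, AmoA, CoxL, group 4 [NiFe]- and [FeFe]-hydrogenases; 70%
for PsbA and IsoA; 75% for HbsT; 80% for PsaA; 40% for energy-converting
rhodopsins; 50% otherwise). Ribosomal hits are retained at coverage ≥ 80%
and bitscore ≥ 40. The two coverage comparisons deliberately differ in
strictness, mirroring the two published phrasings, and boundary rows are
kept as test fixtures. One read with several retained hits to a family
keeps only its best-bitscore hit, preventing multi-HSP double counting.
Reference lengths in the registry are three times a typical protein length
per family; the registry shipped in `inst/extdata/` is package-constructed
(the authoritative 51-family databases and the 14-gene ribosomal set live
in external resources), with family names and threshold classes matching
the field's standard markers.

**Counting noise.** With genome size $G$ and carrier fraction $f$, the
expected on-target read count is $\lambda \approx N f L / G$ and the
per-sample estimate has standard deviation $\approx 100 f/\sqrt{\lambda}$
percentage points. At the generator's defaults ($G = 3$ Mb, $L \approx
1.8$ kb) a $10^6$-read library gives $\lambda \approx 480$ at $f = 0.8$,
i.e. a noise floor of ±3.7 points for a single sample; sub-point precision
at high carriage needs $10^7$-read libraries, which is what real surveys
use. The synthetic gradient therefore validates zone *means* and
monotonic ordering rather than demanding sub-noise accuracy from single
samples.

## H₂ uptake kinetics

Headspace mixing ratios in a sealed vial follow a first-order draw-down
towards an equilibrium floor,

$$C(t) = C_\mathrm{eq} + (C_0 - C_\mathrm{eq})\,e^{-kt},$$

fitted by bounded nonlinear least squares ($k \ge 0$, $C_\mathrm{eq} \ge
0$). Initialization uses the first point for $C_0$, `min(last, 0.53)` for
the floor (the atmospheric H₂ mixing ratio is a prior guess only — the
fitted floor is free), and a log-linear regression for $k$. Three
conditions trigger a linear fallback, with the model choice logged:
non-convergence; a fitted decay spanning less than 10% of the window
($k\,t_{max} < 0.1$), which leaves $k$ and $C_\mathrm{eq}$ jointly
unidentified; and a fitted decay amplitude below three residual standard
deviations, without which the exponential chases measurement noise on
near-flat series (blank vials are the canonical case). The fallback slope
uses the whole window: a series that reaches the fallback is near-linear
throughout, and a short-prefix slope is several-fold noisier.

Initial rates convert to moles through the ideal gas law
($\mathrm{nmol} = \mathrm{ppmv}\cdot 10^{-6} \cdot PV/RT \cdot 10^9$;
10 ppmv in a 120 mL vial at 298.15 K and 101325 Pa is 49.05 nmol), then to
bulk rates per gram of soil with the blank's rate subtracted, floored at
zero with a flag. Cell-specific rates divide by 16S copies per gram
(amol copy⁻¹ h⁻¹); copies stand in for cells with no per-genome copy-number
correction, matching the proxy the field reports. Zone contrasts are
reported both as ratios of zone means and, for the paired wet/dry
hydration contrast, as means of per-sample ratios; the latter follows each
sample's own stimulation but destabilizes when a dry rate sits at the
detection limit, so detection-limited pairs are excluded and the ratio of
means is the robust headline.

Uncertainty on $k$ comes from a parametric bootstrap under a relative
(multiplicative) error model — chromatographic noise grows with the mixing
ratio — with the residual scale estimated from the fit with a
degrees-of-freedom correction. An additive iid residual bootstrap
under-covers badly here because it pools large early-point residuals with
small late-point ones.

**Design of the simulated incubations.** Wet microcosms are monitored for
48 h (12 points), dry ones for 240 h: dry rates are 26-fold lower and on a
2-day window would sit below the 2%-proportional noise floor of the
chromatograph. Sampling until several half-lives of draw-down is also what
keeps $k$ identifiable at small rate constants — the recovery tests use
grids spanning ~5 half-lives of each true $k$.

## qPCR quantification

The plasmid standard series is fitted by ordinary least squares of mean
quantification cycle on $\log_{10}$ copies, averaging replicates on the Cp
scale (matching how plate software reports standards). Amplification
efficiency is $10^{-1/\mathrm{slope}} - 1$; a slope of $-1/\log_{10} 2
\approx -3.32$ is exact doubling. Samples invert the curve on their mean
Cp, flagging extrapolation beyond the standard range, and scale to copies
per gram through the extraction chain (template volume, elution volume,
extracted mass — configurable constants, defaulting to 2 µL / 100 µL /
0.25 g, since the study-level values are unpublished; absolute copies per
gram therefore carry a configurable constant).

## ¹⁴C fixation partitioning

Scintillation counts convert to fixed carbon through
$\mathrm{nmol\,C} = (\mathrm{DPM}/2.22\times 10^6)/SA \times 10^3$ with the
specific activity $SA$ in µCi µmol⁻¹. The stock's printed unit
("mCi nmol⁻¹") is three orders off the standard scale for NaH¹⁴CO₃ and is
interpreted as mCi mmol⁻¹ (≡ µCi µmol⁻¹); the interpretation is a
configurable argument, not a silent assumption. Net rates subtract the
paired heat-killed control — which removes any additive abiotic constant,
an invariance the tests assert — and divide by soil mass and the 96-h
incubation (constant-rate assumption; no saturation correction). The
three-treatment design then partitions: dark assimilation is the dark
rate; photosynthetic fixation is light minus dark; hydrogenotrophic
fixation is (dark + H₂) minus dark. Negative components are floored with a
flag. No correction is applied for dilution of the label by ambient CO₂,
so outputs are minimum fixation estimates.

## Diversity statistics

These are implemented from first principles (vegan serves only as an
independent cross-check in the test suite):

* **Rarefaction** is a single seeded draw without replacement per sample
  (the study normalized once; averaging draws would shrink variance
  artificially); samples below depth are dropped with a warning.
* **Chao1** defaults to the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined for all inputs; the classic
  form is selectable for comparability with other toolchains and falls
  back when $F_2 = 0$. Which variant the original toolchain used is not
  documented, hence both.
* **Bray–Curtis**, **PCoA** (Gower double-centering; negative eigenvalues
  reported, excluded from coordinates; axis signs fixed by making each
  axis's largest-magnitude loading positive so ordinations reproduce
  across platforms).
* **PERMANOVA** uses the $(b+1)/(m+1)$ permutation p-value convention on
  raw label permutations, with exhaustive enumeration available for small
  n (the tests compare it against a brute-force enumeration oracle).
* **PERMDISP** embeds the dissimilarity matrix with imaginary axes
  retained, measures distances to group spatial medians with the standard
  imaginary-part correction, and permutes group labels over those
  distances (medians are not recomputed per permutation, the same scheme
  vegan uses). With spatial medians the test is conservative for groups
  of ~6 — vegan behaves identically under the same simulations — and is
  well calibrated from about 12 per group, which is the size the
  calibration tests use.
* **SIMPER** decomposes the average between-group Bray–Curtis into
  per-taxon contributions; their sum equals the mean between-group
  dissimilarity to numerical precision (asserted at $10^{-9}$), and
  permutation p-values give the chance of an equal-or-larger contribution
  under label shuffling.

## Gradient statistics

Kruskal–Wallis (tie-corrected, chi-square reference) is the omnibus test
across zones, with Dunn z statistics from pooled rank means and
Benjamini–Hochberg adjustment for post-hoc pairs. Predictor screening is
two-stage: while any pair of predictors has squared Pearson correlation
above 0.8, the member with the higher mean absolute correlation to the
others is dropped (the published procedure does not state which member was
removed; this rule is deterministic and keeps the more independent
predictor), then predictors with variance inflation factors ≥ 5 are
removed iteratively, ties broken by name order. The screen's exit state
always satisfies both criteria, which the tests assert post hoc. Screened
predictors feed single-predictor ordinary least squares. Negative-binomial
GLMs for richness/abundance are noted but out of scope; the rank-based
tests cover the rate comparisons this package reproduces.

## The synthetic generator

Every generator is a pure function of its parameters and a seed. The
community generator assigns carrier genomes by half-to-even rounding of
`carrier_fraction * n_genomes` (deterministic and unbiased across
fractions), gives every genome exactly one copy of each of the 14
ribosomal genes, and draws abundances uniform or lognormal. Hit tables
realize per-family Poisson counts at the expected rate
$N \sum_g a_g c_g L / \sum_g a_g G_g$, with identities clamped just above
threshold so that at zero decoy rate every hit passes filtering; decoys are
drawn strictly below the discriminating threshold of their family class
(identity for metabolic, bitscore for ribosomal) and carry a `DECOY` label
in the subject accession so filtering tests are exact, never statistical.
The gradient dataset encodes the study conditions: group 1l hydrogenase
carriage rising 6→80% across zones, 16S copies declining 61-fold,
cell-specific H₂ uptake spanning 100× wet with dry rates 26-fold lower,
photosynthesis-dominated fixation in wet zones shifting to
hydrogenotrophic dominance with aridity, and zone-shifted multinomial OTU
tables. Per-sample heterogeneity is lognormal with log-sd 0.3 (mean-one
correction applied), a typical between-replicate spread for soil assays.

What the generator does **not** emulate: read-level sequence content (no
FASTQ), alignment ambiguity between homologous families, compositional
coupling between markers, PCR inhibition, chromatogram drift, or spatial
autocorrelation between samples. Passing recovery tests therefore shows
the estimators are correct under their stated assumptions, not that those
assumptions hold in any particular field dataset.

## Problem sizes and numerical choices

The default validation runs use 24 samples (4 zones × 6), 2×10⁵-read
libraries over 300-genome communities, 12–13-point gas series, 999
permutations for all permutation tests, and 500 null simulations for
calibration checks; the estimator-recovery tests use 10⁶-read libraries
and 20 seeded replicates per setting. Tolerances: closed-form identities
at 10⁻⁹–10⁻¹²; noiseless generative recovery at 10⁻⁶ relative or better;
stochastic recoveries at the scale of their analytic sampling noise. All
TSV output uses tab separation, "." decimals, LF endings, and
deterministic row ordering, so identical configurations reproduce
byte-identical outputs.

## Known limitations

* Percent-of-community estimates inherit the one-copy-per-genome
  assumption; multi-copy families inflate estimates proportionally.
* Single-sample estimates at high carriage carry several percentage
  points of counting noise at desk-scale depths (see the arithmetic
  above).
* Absolute copies per gram depend on unpublished extraction constants and
  should be compared only within a study.
* The exponential-floor model assumes a single first-order consumer pool;
  biphasic kinetics would be mis-summarized by one $k$.
* Fixation rates are minimum estimates over a 96-h window under a
  constant-rate assumption.
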