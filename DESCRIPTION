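Package: desertprod
Title: Chemosynthetic and Photosynthetic Primary Production Along Desert Aridity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational chain behind desert
    aridity-gradient microbiome studies: estimating the fraction of a soil
    community encoding metabolic marker genes from short-read homology hits
    normalized to universal single-copy ribosomal genes; fitting first-order
    trace-gas (H2) draw-down kinetics and converting them to bulk and
    cell-specific oxidation rates; absolute 16S rRNA gene quantification from
    qPCR standard curves; partitioning 14C-CO2 fixation into dark,
    photosynthetic, and hydrogenotrophic components; and the accompanying
    community-ecology statistics (rarefaction, Chao1, Bray-Curtis, PCoA,
    PERMANOVA, PERMDISP, SIMPER, Kruskal-Wallis with Dunn/BH post hoc, and
    collinearity/VIF predictor screening). A seeded synthetic-data generator
    produces every input with known ground truth so each estimator can be
    validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
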