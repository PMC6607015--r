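Package: lbpascreen
Title: High-Content Screen Analysis for Endosomal Lipid Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for image-based high-content
    screens of endosomal lipids (LBPA and cholesterol). Generates synthetic
    384-well plate images with known ground truth, segments nuclei, cells and
    LBPA-positive endosomes (top-hat spot detection, perinuclear annulus
    masks), extracts a 50-feature per-cell measurement vector, normalizes
    wells to DMSO controls (Z-scores), applies a toxicity filter, computes
    z-prime assay-quality factors, embeds compound phenotypes by PCA and
    classifies compounds as LBPA-selective versus dual-lipid hits. Also
    implements the downstream tabular arithmetic of such studies: mol% of
    total phospholipid, acyl-chain species grouping, ratio features and
    comparative-CT fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
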