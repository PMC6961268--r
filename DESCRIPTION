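Package: edscape
Title: Spatially Resolved Quantification of A-to-I RNA Editing from In Situ Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for image-based in situ sequencing
    (ISS) of RNA editing sites. Decodes 4-nt probe barcodes from multi-cycle
    fluorescence intensities with per-base quality scores, detects rolling
    circle amplification products by top-hat enhancement and watershed
    separation, segments nuclei from DAPI and expands them to cell somata,
    assigns reads to cells and anatomical regions of interest, and computes
    per-site A-to-I editing levels, regional and cell-type editing ratios,
    active/inactive Adar2 isoform decomposition, a single-cell mixed-cell
    observed-versus-expected heterogeneity analysis, and rank-based group
    comparisons (Kruskal-Wallis with Dunn-Sidak post hoc tests). Ships a
    synthetic ISS scene generator with ground truth so every stage is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
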