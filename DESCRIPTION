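Package: qwaseg
Title: Evaluation of Cell Instance Segmentation for Quantitative Wood Anatomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate instance segmentation of xylem cell lumina in
    transversal wood-section images. Matches predicted cells to ground-truth
    cells by overlap, classifies split (disconnected positive) and merge
    (merged negative) errors, excludes border-clipped cells, and computes
    per-cell lumen-area pixel precision, recall and F1 together with
    instance-level confusion statistics, size-class histograms of missed
    cells, and colour-coded error maps. Includes a model-agnostic tiled
    inference pipeline with dual-resolution merging for ring-porous species,
    a classical watershed baseline segmenter, and a synthetic wood-section
    generator (conifer, diffuse-, semi-diffuse- and ring-porous types, with a
    slide-artifact catalogue and an exact error-injection oracle) so every
    component is testable without trained network weights or real slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
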