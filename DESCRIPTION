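Package: SliceQuant
Title: Automated Whole-Slide Immunofluorescence Quantification for Tissue Slice Cultures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of multichannel whole-slide fluorescence
    images of organotypic tissue slice cultures. Builds tissue, nuclei (DAPI)
    and marker (Ki67 or TUNEL) masks by global histogram thresholding (Otsu's
    between-class-variance criterion and Kapur's maximum-entropy criterion,
    both implemented from scratch), restricts marker signal to nuclei, clears
    sub-nuclear specks by connected-component size, and reports per-image area
    ratios (proliferating or apoptotic area per nuclear area, nuclear area per
    tissue area) with per-slice aggregation, group statistics (Kruskal-Wallis
    with Dunn's post-hoc tests), and manual-vs-automatic validation by Spearman
    correlation. Includes linear spectral unmixing for channel bleedthrough and
    a synthetic slide generator with exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: CellBiology, ImageImport, Segmentation, Visualization
RoxygenNote: 7.3.3
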