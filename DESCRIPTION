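Package: stainplex
Title: Whole-Slide Multiplex Immunostaining Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tile-based analysis of whole-slide multiplex immunostaining
    (iterative chromogenic staining such as MICSSS, singleplex IHC, and
    multichannel immunofluorescence). Provides colour deconvolution of
    chromogenic stains, tissue masking and overlap-padded tiling, coarse
    plus affine/elastic co-registration of staining iterations on the
    deconvolved nuclear channel, composite nuclear segmentation by
    centroid consensus across iterations, per-cell per-compartment
    feature quantification, unsupervised cell classification
    (mini-batch k-means and a Gaussian-mixture alternative) with
    cluster-level binarization, compartment reconciliation from GeoJSON
    annotations, nearest-neighbour proximity statistics, validation
    metrics against manual point annotations, and a ground-truthed
    synthetic slide generator so the whole pipeline is testable without
    clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    mclust,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
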