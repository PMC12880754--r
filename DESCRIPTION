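Package: glomscale
Title: Hierarchical Multiscale Segmentation and Morphometry of Glomeruli in 3D Organ Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for propagating segmentations of small quasi-spherical functional
    units (kidney glomeruli) from high-resolution 3D volumes of interest to
    lower-resolution whole-organ scans. Provides a synthetic multiscale kidney
    phantom with known ground truth, volume preprocessing (slice-wise CLAHE,
    bit-depth conversion, patch extraction, per-sample train/test splits), a
    pluggable patch-based segmentation backbone trained with a combined
    cross-entropy and soft-Dice loss with exponential-moving-average validation
    tracking, instance-level false-positive filtering with Latin-hypercube
    threshold search, staged exhaustive-plus-quasi-Newton rigid registration
    across resolutions under a mutual-information metric, pseudo-label
    propagation, and whole-organ morphometry (summation-kernel density maps,
    tripartite cortical zonation, zonal statistics with Kruskal-Wallis tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    lhs,
    jsonlite,
    RNifti,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
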