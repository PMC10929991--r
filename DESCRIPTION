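Package: ssdect
Title: Automated Size-Specific Dose Estimates for Thoracic CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes size-specific dose estimates (SSDE) for axial thoracic
    CT slices from the volumetric CT dose index (CTDIvol) and patient size.
    Patient size is measured two ways: the TG220 water-equivalent diameter
    from the mean CT number and area of the body region, and a corrected
    effective diameter in which the anterior-posterior and lateral body
    dimensions are re-weighted by the relative electron densities of lung,
    soft tissue and bone. Tissue classes come either from a deterministic
    Hounsfield-unit threshold segmenter or from a trainable four-class
    residual U-Net. A synthetic elliptical thorax phantom generator with
    closed-form ground truth makes the whole pipeline testable without
    patient data, and agreement statistics (regression, Pearson correlation,
    percentage difference, Bland-Altman) compare SSDE variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
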