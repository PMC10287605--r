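Package: lemap
Title: Voxel-Wise Local Entropy Maps for Volumetric CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise local Shannon entropy maps of volumetric CT
    images with a sliding cubic kernel, Gaussian smoothing and normalization
    to a liver-parenchyma reference; extracts first-order histogram statistics
    within volumes of interest; operationalizes a four-class intra-tumoral
    entropy-pattern classifier (homogeneous, inhomogeneous, peripheral rim,
    mixed); and provides a seeded digital-phantom generator, a kernel-size
    sensitivity sweep, slice/fusion rendering and a pipeline entry point, so
    the whole workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    oro.nifti,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
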