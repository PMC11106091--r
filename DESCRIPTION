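Package: octafractal
Title: Fractal Dimension and Lacunarity Analysis of OCTA Capillary Plexus Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the geometry of retinal capillary networks on en-face
    optical coherence tomography angiography (OCTA) slabs. Grayscale slabs of
    the superficial and deep capillary plexus are median-filtered, binarized
    with Otsu's method and thinned to one-pixel skeletons; fractal dimension
    is estimated by multi-origin box counting and lacunarity by the
    gliding-box statistic. A calibrated synthetic-cohort generator emulates
    diabetic macular edema eyes with graded peripheral capillary dropout, and
    a statistics stage provides two-group comparisons (Welch t) and Pearson
    correlations of fractal metrics against non-perfusion extent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
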