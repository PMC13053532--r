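Package: xparr
Title: Transmittance Depth-Map Texture Indices for Radiographic ROIs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative grayscale texture analysis for rectangular regions of
    interest on dental radiographs. Computes a per-pixel transmittance depth map
    from row-normalized gray levels and summarizes it into scalar indices (Xpar,
    Power Xpar, Pixel Count) under native-resolution and digitally magnified
    viewing conditions. Includes a synthetic dentin-pulp phantom and cohort
    generator, digital zoom by pixel interpolation (nearest, bilinear, bicubic),
    Sobel gradient maps, minimal grayscale DICOM/PNG/TIFF input, nonparametric
    group comparisons with rank-biserial effect sizes, paired zoom comparisons,
    ROC analysis with Youden-optimal thresholds, multivariable logistic models,
    and a-priori sample-size design via the noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
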