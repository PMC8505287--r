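Package: ihcspat
Title: Spatial Point-Pattern Analysis of Immunostained Cells in Brightfield
    Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the spatial distribution of immunostained
    (DAB-positive) inflammatory cells in brightfield immunohistochemistry
    fields. Separates hematoxylin and DAB stains by colour deconvolution in
    optical-density space, thresholds the unmixed channels to extract
    positive-cell coordinates and the immunoreactive area fraction, and
    characterizes the resulting point patterns with a nearest-neighbour
    uniformity index and Ripley's K-function compared against Monte-Carlo
    envelopes from matched complete-spatial-randomness simulations. Includes
    a synthetic-data generator producing two-stain fields with known
    ground truth and full two-arm cohorts, and sample-level two-group
    comparison by Student's t-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    graphics,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
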