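Package: dyespec
Title: Hyperspectral and Visible-Light Characterization of Tattoo Dyes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reflectance characterization of permanent-makeup and tattoo dyes
    for laser-treatment planning. Calibrates ENVI-style hyperspectral cubes
    (400-1000 nm, 128 bands) against an 18% gray reference panel, extracts
    region-of-interest mean spectra and locates each dye's wavelength of
    maximum reflectance by three-point parabolic refinement. Quantifies the
    spatial homogeneity of dried dye smears in visible light via the
    horizontal gray-level co-occurrence matrix (contrast and homogeneity) and
    their cross-dye Pearson correlation. Ships a synthetic-scene generator
    (Gaussian spectral model, exact neighbor-difference texture synthesis) so
    the full pipeline is testable without original imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
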