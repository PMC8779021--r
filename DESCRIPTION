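Package: viabquant
Title: Automated Live/Dead Viability Quantification from Confocal Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bacterial viability from dual-marker (SYTO9/propidium
    iodide) confocal micrographs without cell segmentation. Images are converted
    to HSV colour space and the brightness (V) channel histogram, normalized to
    the number of zero-brightness (dark background) pixels, yields a per-image
    feature -- by default the maximum of a 127-bin partition of the nonzero
    brightness levels -- whose green/red quotient estimates the viable to
    non-viable cell ratio of a stained sample. Includes a seeded synthetic
    confocal image simulator (Thomas-type clustered Gaussian spots) with known
    ground truth for validation, and a standardized (correlation-matrix) PCA
    with biplot tables for integrating reactor-level chemical and biochemical
    variables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
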