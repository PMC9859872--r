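Package: lfaquant
Title: Quantification and Calibration of Lateral Flow Assay Strip Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative readout of multi-channel lateral flow
    immunoassay (LFA) strips in the competitive (binding-inhibition) format.
    Provides a synthetic strip-image, spectrum and size-distribution generator
    with ground truth; green-channel signal extraction with fiducial-based
    zone localization, planar illumination correction and Otsu segmentation;
    four-parameter logistic calibration with delta-method confidence bands
    and confidence-band-derived detection limits (MDC/RDL); and the standard
    antibody-gold-nanoparticle conjugate characterization calculations
    (coupling stoichiometry, monolayer capacity, UV-Vis yield and plasmon
    peak shift, DLS number-mean diameter and layer thickness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
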