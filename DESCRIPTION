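Package: fovmorph
Title: Foveal OCT Morphometry and Normative Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying foveal topography and microstructure from
    macular optical coherence tomography (OCT) B-scans. Implements flattening
    of scans to the posterior retinal pigment epithelium boundary, automatic
    detection of the foveal centre (photoreceptor inner/outer-segment peak)
    and of the foveal wall maxima (rim points of maximal ganglion cell +
    inner plexiform layer thickness), and extraction of foveal depth and
    layer-thickness parameters. Includes a synthetic B-scan and cohort
    generator calibrated to published summary statistics for full-term
    control eyes and extremely preterm born eyes without retinopathy of
    prematurity, normative mean +/- 2 SD classification, and the associated
    statistical analyses (normality testing, Pearson correlation matrices,
    layer-proportion summaries, Welch group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
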