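Package: phcDepth
Title: Depth-Resolved Quantification of Phenolic-Compound Fluorescence in
    Leaf Cross-Sections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the depth-resolved localization of phenolic-compound
    (PhC) fluorescence in RGB micrographs of leaf cross-sections stained with
    Naturstoff reagent A. Yellow flavonoid fluorescence is isolated from red
    chlorophyll and blue cell-wall autofluorescence by hue-window
    segmentation in HSV space; the mesophyll is delimited per image column
    from the chlorophyll signal (excluding the epidermis) and vascular
    bundles are masked out via their blue autofluorescence; five equally
    spaced vertical transects with a shared uniform random offset
    (systematic uniform random sampling) are read out and binned into five
    mesophyll depth layers (AD, UM, MM, LM, AB); layer means are aggregated
    over transects, sections and replicates and analyzed by factorial
    fixed-effects ANOVA with Fisher's LSD letter groupings. A synthetic
    half-lamina micrograph generator with analytic ground-truth depth
    gradients, treatment-dependent effect sizes and a diurnal light-regime
    model supports end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'spectral.R'
    'geometry.R'
    'profiling.R'
    'synth.R'
    'stats.R'
    'config.R'
    'io.R'
    'pipeline.R'
    'phcDepth-package.R'
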