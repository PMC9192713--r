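Package: cortmag
Title: Cortical Magnification and Contrast-Sensitivity Asymmetries Around the Visual Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking population receptive
    field (pRF) derived cortical magnification in primary visual cortex (V1)
    to contrast sensitivity measured around the visual field. Provides
    synthetic triangulated hemisphere meshes with ground-truth retinotopy and
    tunable polar-angle asymmetries, a bar-aperture retinotopic mapping
    stimulus, a 2D-Gaussian pRF forward model with coarse-to-fine fitting,
    wedge-ROI surface-area (cortical magnification) measurement on cortical
    meshes, adaptive 3-down-1-up PEST staircase simulation of 2AFC contrast
    thresholds, and horizontal-vertical / vertical-meridian asymmetry indices
    with permutation null distributions for pooled Spearman correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'mesh.R'
    'stimulus.R'
    'prf.R'
    'bold.R'
    'staircase.R'
    'cohort.R'
    'cortmag-package.R'
    'io.R'
    'stats.R'
    'wedge.R'
    'pipeline.R'
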