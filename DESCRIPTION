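Package: msiatlas
Title: Computational Atlas Construction for Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds computational atlases from mass spectrometry imaging
    (MSI) experiments. Reads per-pixel spectra from imzML, quantizes them
    into fixed-bin cubes with total-ion-current normalization, refines
    m/z peak centers with intensity-weighted Gaussian mixtures, rasterizes
    polygon region annotations, trains ensembles of variational Bayesian
    logistic classifiers to measure category confusion, mines region-m/z
    associations by noise-calibrated stability selection and pairwise-AUC
    ranking, assembles a confusion-weighted category graph with a 2-D
    spectral embedding, and renders virtual landscape and virtual
    pathology stain images. A synthetic phantom generator with known
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    xml2,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pracma,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'annotations.R'
    'binning.R'
    'bayes.R'
    'atlas.R'
    'imzml.R'
    'mining.R'
    'msiatlas-package.R'
    'phantom.R'
    'render.R'
    'refine.R'
    'pipeline.R'
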