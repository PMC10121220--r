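Package: scfunctype
Title: Functional Cell-Type Classification from Calcium Imaging of the
    Mouse Superior Colliculus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for classifying visual neurons of the mouse
    superior colliculus into functional types from two-photon calcium
    imaging responses. Converts raw fluorescence to trial-aligned
    delta-F/F, gates neurons by response reliability (SNR), computes a
    battery of selectivity indices (direction/orientation selectivity,
    habituation, looming, contrast, size tuning, color preference,
    receptive-field size), builds a 54-dimensional sparse-PCA feature
    matrix, clusters it with Gaussian mixture models selected by BIC,
    scores cluster stability by subsampling Jaccard and co-association
    statistics, quantifies the anatomical arrangement of the resulting
    types with density recovery profiles and bootstrap separation tests,
    and decomposes collicular type responses as linear combinations of
    retinal ganglion cell type responses. Includes a synthetic-data
    generator that emulates the statistical structure of such recordings
    so the whole pipeline is testable without raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    minpack.lm,
    ape,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
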