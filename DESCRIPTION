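Package: mesokit
Title: Analysis Toolkit for Mesoscale Two-Photon Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of mesoscale two-photon microscopy
    experiments: 3D vascular morphometry from centerline skeletons
    (segment diameter, length, inter-vessel distance, volume density),
    calcium fluorescence processing (neuropil subtraction, percentile
    baseline dF/F, SNR), locomotion-state-resolved functional
    connectivity graphs with thresholded Pearson correlations and
    graph-theoretic summaries, a sensorless modal adaptive-optics
    simulator with a Fourier-optics two-photon forward model, and
    bead-stack PSF resolution characterization. Includes synthetic-data
    generators with known ground truth for every analysis path.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
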