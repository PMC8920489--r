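Package: oisconn
Title: Autocorrelation-Corrected Statistics for Optical Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical significance testing for pixel-wise resting-state
    functional-connectivity matrices from widefield optical intrinsic signal
    (OIS) imaging of the mouse cortex. Pearson correlations between
    hemodynamic time courses are converted to z scores via the Fisher
    transform with variance estimated three ways: naive (independent
    samples), Bartlett's effective-degrees-of-freedom correction based on
    per-pixel temporal autocorrelation times, and the pairwise xDF estimator
    built from full auto- and cross-correlation sequences. Spatial
    multiplicity over the correlation matrix is controlled with the
    Benjamini-Yekutieli false-discovery-rate procedure, including FDR
    sensitivity maps. Includes the standard preprocessing chain (Gaussian
    spatial smoothing, zero-phase bandpass and downsampling, global signal
    regression, parcel averaging, run concatenation) and a synthetic-data
    generator with planted correlation networks and known autocorrelation
    for validation without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
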