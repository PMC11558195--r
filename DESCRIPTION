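Package: hemospm
Title: Multivariate Statistical Process Monitoring of Postoperative
    Hemodynamic Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring postoperative vital-sign trajectories
    with multivariate statistical process control, as used for batch
    industrial processes.  Implements 1-minute grid resampling, dropout
    detection and Hampel outlier cleaning of high-frequency vital-sign
    streams, batch-wise trajectory normalization over a patients x
    signals x time array, latent-variable models based on principal
    component analysis and slow feature analysis, and Hotelling T2 /
    squared-prediction-error control charts with chi-square based control
    limits, evaluated under leave-one-out cross-validation.  Includes a
    synthetic multi-patient cohort generator with known ground truth so
    the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
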