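Package: astrodetect
Title: Adaptive Detection of Weak Astrocytic Calcium Events in
    Two-Photon Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A low-parameter adaptive framework for detecting weak,
    transient, background-coupled astrocytic calcium events in
    two-photon fluorescence video. Preprocessing (sliding-window frame
    accumulation, static background subtraction with normalization,
    Gaussian smoothing, optional generalized Anscombe transform)
    stabilizes input statistics; the detection core combines
    segment-wise Gaussian mixture modeling with BIC model selection,
    temporal-persistence masking, and heuristic adaptive updates of the
    global and local thresholds and the mixture re-estimation period.
    Ships a synthetic two-photon video generator (procedural cellular
    skeleton background, moving-spot events, mixed Poisson-Gaussian
    noise) with event-level ground truth, plus evaluation metrics
    (block-statistics and wavelet-MAD noise estimates, local and
    reference SNR, Dice coefficient) and an experiment driver for
    replicate studies and parameter-sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
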