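Package: l5topo
Title: Tonotopy and Ensemble Analysis of Layer-5 Auditory Cortex Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of two-photon and widefield calcium imaging of
    layer-5 auditory cortex. Implements widefield delta-F/F best-frequency
    mapping with reversal-point and cortex-boundary detection, per-neuron
    responsiveness screening, unimodal/bimodal gaussian tuning classification
    with bandwidth, best- and center-frequency estimates, local tonotopic
    heterogeneity (interquartile range within a 100-micrometre radius), and
    correlation-based ensemble clustering with a dynamic hybrid tree cut and a
    label-shuffle null. Includes synthetic-data generators with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    mclust
Config/testthat/edition: 3
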