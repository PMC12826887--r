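Package: ppgrisk
Title: Pulse Waveform Morphology and Cardiovascular Risk Modelling
Version: 0.1.0
Authors@R:
    person("Waveform", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extraction of morphological indices from photoplethysmogram
    (PPG) pulse waveforms via fiducial points on the waveform and its first
    and second derivatives, followed by standardized and elastic-net
    penalized Cox proportional-hazards modelling of incident cardiovascular
    events, with concordance-based incremental-prediction evaluation.
    Includes a synthetic PPG beat and survival-cohort generator with known
    ground truth so every pipeline stage can be validated against an oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
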