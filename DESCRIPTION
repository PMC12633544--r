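Package: rheostim
Title: Digital Twin of a Rheostatic Closed-Loop Neurostimulation Device
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of a circadian-scheduled ("rheostatic")
    closed-loop neurostimulation implant, together with a virtual test bench
    and seeded physiological signal generators. Emulates the embedded
    per-sample signal chain (first-order IIR offset removal, fourth-order IIR
    band-pass, rectification, exponential-moving-average smoothing) that
    turns a biopotential stream into a power-in-band envelope; a debounced
    single-threshold classifier driving a ramped constant-current stimulation
    engine; a 48-slot circadian scheduler over two configuration profiles
    with a circular loop recorder; an additive stimulation-artefact bench for
    causal sense-classify-stimulate loops; and surrogate-based (Bayesian)
    optimisation of filter and classifier parameters against precision-recall
    AUC on labelled data. Includes generators for diurnally modulated beta
    bursts, electrographic seizures, gamma-band sleep epochs, theta-alpha
    drowsiness events and triaxial motion, so control policies can be tuned
    and validated end-to-end without hardware or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
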