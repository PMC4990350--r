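Package: calsens
Title: Live-Tissue Calcium Response Quantitation for Parathyroid Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitation of live-cell calcium flux responses in intact
    tissue-slice fluorescence time series. Provides a ground-truthed
    synthetic movie generator, nuclei and flux-object detection with
    physical-unit size and edge filters, corrected total cell fluorescence
    (CTCF) trace extraction, kinetic waveform classification including the
    maximal-responder definition and ionomycin viability control,
    four-parameter logistic dose-response fitting with calcium EC50,
    rigid live/fixed field registration with Costes-randomization
    colocalization, and calcium-dependent parathyroid hormone suppression
    and one-phase exponential decay kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
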