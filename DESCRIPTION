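Package: bandfocus
Title: Band-Branched EEG Motor-Imagery Decoding with Attention, Explainability and Spectral Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-trial EEG motor-imagery decoding for natural versus
    supernumerary effectors. Implements a lightweight band-branched
    convolutional classifier with squeeze-and-excitation channel attention
    and layer normalisation, a leave-one-subject-out evaluation harness,
    Shapley-value channel/time attributions with scalp topography export,
    event-related spectral perturbation (ERSP) analysis with paired
    bootstrap statistics, and a multi-subject synthetic motor-imagery EEG
    simulator with planted, ground-truth spectral effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
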