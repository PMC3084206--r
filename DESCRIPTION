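Package: luxrate
Title: Transcription-Rate Inference from Destabilized Luciferase Reporter Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure the rate of transcription from plate-reader
    time courses of bacterial strains carrying destabilized firefly
    luciferase promoter fusions. Provides a generative simulator of diauxic
    batch growth with passive RNA-polymerase reallocation, unstable-reporter
    kinetics and Spo0A~P-driven target promoters; readers and
    quality-control utilities for dual-channel (OD600, luminescence)
    plate-reader tables; Savitzky-Golay growth-rate derivation and reporter
    deconvolution; detection and phase analysis of growth-rate pauses and
    transcriptional bursts; and frequency statistics for rare developmental
    transitions such as competence and sporulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
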