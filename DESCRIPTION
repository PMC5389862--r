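Package: chirpinv
Title: Phase-Invariant Coding and Detectability of Electrocommunication Chirps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for studying how weakly electric
    fish communication chirps are represented in peripheral electrosensory
    afferent activity across background beat frequencies. Synthesizes beat
    amplitude modulations with embedded chirps at controlled beat phases,
    simulates P-unit-like afferent spike trains with high-pass gain and
    rectification, and computes peristimulus time histograms, phase-locking
    indices, time-resolved pairwise spike-count correlations over beat-scaled
    sliding windows, waveform distances, chirp detectability, phase-invariance
    scores, response-duration power-law fits, and behavioral echo-chirp
    analyses with block-bootstrap errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
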