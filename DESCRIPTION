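Package: cvep
Title: Spatiotemporal LCMV Beamformer Decoding of Code-Modulated Visual
    Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decoding pipeline for code-modulated visual evoked potential
    (cVEP) brain-computer interfaces. Generates and validates m-sequence
    stimulation codes with per-target circular lags, preprocesses raw
    multichannel EEG (mastoid re-referencing, 4-31 Hz zero-phase Butterworth
    filtering, epoching, downsampling), trains one linearly-constrained
    minimum-variance (LCMV) spatiotemporal beamformer per target from
    single-presentation EEG segments, classifies epochs one-vs-all with
    ROC-optimised thresholds, and evaluates target-identification accuracy
    and information transfer rate under stratified cross-validation with
    greedy forward channel selection. Includes a synthetic cVEP session
    simulator (lag-coded evoked responses in coloured EEG-like noise) so the
    full pipeline is testable without recorded data, plus BrainVision and
    EDF+ readers/writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
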