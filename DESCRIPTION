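Package: pcgsnr
Title: Signal-to-Noise Quality Assessment for Phonocardiographic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-heartbeat signal-to-noise ratio (SNR) quality assessment of
    phonocardiogram (PCG) recordings segmented against a simultaneous ECG,
    calibrated additive-Gaussian-noise degradation of recordings on a 0.1 dB
    schedule, and determination of the minimum acceptable SNR that keeps
    heart-valve-closure latency estimates (mitral, tricuspid, aortic,
    pulmonary components of the first and second heart sounds) within a
    chosen uncertainty, using a Wald-Wolfowitz runs-test trend criterion.
    Includes a synthetic PCG+ECG cohort generator with ground truth so the
    whole pipeline is testable without access to clinical recordings, plus
    readers/writers for WAV, WFDB-style and CSV record formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
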