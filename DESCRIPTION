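Package: itfx
Title: Individual Theta Frequency Extraction from Task EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a person's individual theta frequency (ITF) from EEG
    recorded during associative-memory encoding. Implements complex Morlet
    wavelet time-frequency decomposition, event-related spectral perturbation
    (ERSP) as a ratio to a pre-stimulus baseline, an overlapping time-window by
    electrode peak-frequency matrix, modal theta-band extraction with a
    per-person reliability score and five-class reliability scale, a
    parieto-occipital electrode fallback, and a resting-state control contrast.
    Includes readers for EDF and a plain-text fixture container, subsequent-
    memory epoch labeling, automated preprocessing, and a synthetic-EEG
    generator (1/f background, posterior alpha, event-locked theta bursts) so
    the full pipeline is testable without real recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
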