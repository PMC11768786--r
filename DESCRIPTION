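Package: exfatigue
Title: Exercise Fatigue State Discrimination from Surface EMG and ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, preprocessing, feature extraction and classification
    of exercise fatigue states (very relaxed / slightly tired / very tired)
    from wearable surface electromyogram (sEMG) and electrocardiogram (ECG)
    recordings. Provides a calibrated synthetic-signal generator for the three
    Borg RPE fatigue states, digital filters for baseline drift, mains
    interference and motion artifacts, an incremental sliding-window median
    filter for ECG baseline removal, the five standard EMG fatigue indicators
    (ARV, IEMG, RMS, MPF, MF), R-peak detection with heart-rate-variability
    spectral band powers (LF, HF, LF/HF), and a from-scratch long short-term
    memory (LSTM) sequence classifier trained by backpropagation through time,
    together with an end-to-end, seed-reproducible experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
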