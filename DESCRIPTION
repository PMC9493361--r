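Package: neurocpm
Title: Multimodal EEG-fNIRS Resting-State Connectivity and
    Connectome-Based Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds functional connectivity matrices from resting-state
    EEG amplitude-modulation series and fNIRS hemoglobin concentration
    series, predicts a behavioural performance score with leave-one-subject-out
    connectome-based predictive modelling (edge selection at p <= alpha,
    connectivity summary scores, linear support vector regression), and
    quantifies cross-modality coupling of the connectivity profiles with
    permutation tests and false-discovery-rate correction. Includes EEG
    preprocessing (Butterworth broadband filtering, wavelet-enhanced ICA
    artifact correction, Hilbert-envelope amplitude modulation), fNIRS
    preprocessing (linear-phase FIR band-pass, whole-record detrending,
    modified Beer-Lambert law), and a synthetic cohort generator with
    planted, controllable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    ica,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    withr
Config/testthat/edition: 3
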