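Package: ieegnet
Title: Interpretable Convolutional-LSTM Classification of Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies 3-second single-channel intracranial EEG segments as
    physiological, pathological (interictal epileptiform spikes and
    high-frequency oscillations) or artifact (muscle, powerline) with a
    convolutional-LSTM sequence model, and localizes the graphoelements that
    drive each decision through per-sample classification probability
    heatmaps. Includes a synthetic iEEG generator with exact ground-truth
    event intervals, STFT spectrogram preprocessing with per-band z-scoring,
    a Hilbert-envelope candidate event detector for annotation support,
    evaluation metrics (sensitivity, positive predictive value, F1, one-vs-rest
    ROC and precision-recall curves), a minimal EDF reader/writer, and
    command-line entry points for simulation, training, inference and
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
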