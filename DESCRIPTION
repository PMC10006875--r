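Package: vflatent
Title: Low-Dimensional Latent Spaces for Ventricular Fibrillation ECG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying types of ventricular fibrillation (VF) in
    low-dimensional autoencoder latent spaces built from single-lead surface
    ECG recordings. Includes a condition-specific synthetic VF signal
    generator (frequency-modulated oscillators with a spectro-temporal
    "fork"), clipping injection and restoration, decimation and windowing,
    short-time spectral estimation (spectrogram and Welch periodograms
    restricted to the 0-16 Hz VF band), eleven audio-style spectral
    descriptors over linear and psychoacoustic (Mel/Bark/ERB) filterbanks
    capped at 50 Hz, joint-mutual-information feature selection over
    whole-sequence feature tracks, unsupervised and supervised fine-tuned
    autoencoders with softmax heads, and per-class accuracy reporting across
    dataset variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
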