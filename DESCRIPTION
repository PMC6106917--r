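Package: voxscreen
Title: Acoustic Voice Analysis and Rule-Based Dysphonia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the four acoustic parameters most used in clinical
    voice assessment -- fundamental frequency (Yin-style estimator),
    cycle-to-cycle jitter, shimmer, and the harmonics-to-noise ratio
    (cepstral comb-liftering, with an autocorrelation alternative) -- from
    sustained-vowel recordings sampled at 8 kHz, and screens each voice as
    healthy or pathological by comparing every parameter against fixed
    gender-aware healthy ranges.  Includes classification-performance,
    reliability and cross-device dispersion statistics, a deterministic
    synthetic vowel generator with analytically exact jitter, shimmer and
    harmonic-to-noise ground truth for validation, plain-text WAV input and
    output, and a command-line interface covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
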