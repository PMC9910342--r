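Package: subpress
Title: Subglottal Pressure Estimation from Neck-Surface Acceleration
Version: 0.1.0
Authors@R:
    person("Voice", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating subglottal pressure (Ps) from a neck-surface
    accelerometer signal. Implements laboratory calibration against intraoral
    pressure references (sensor calibration lines, polyphase resampling,
    cross-correlation alignment, vowel and pressure-plateau segmentation),
    frame-level accelerometer features (RMS, fundamental frequency with
    subharmonic octave-error correction, cepstral peak prominence, sound
    pressure level), subglottal impedance-based inverse filtering (IBIF) of the
    accelerometer signal to glottal airflow with particle-swarm parameter
    fitting, three Ps estimators (an empirical SPL/f0 formula, a person-specific
    linear model on accelerometer RMS, and a stepwise multiple regression with
    five-fold cross-validation), an ambulatory daylong processing chain with a
    five-criterion voice-activity detector and summary statistics, synthetic
    signal generators with planted ground truth, and a method-comparison
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
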