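Package: mfsense
Title: Sensor-Fusion Assessment of Mental Fatigue from Multichannel
    Physiological Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end framework for assessing mental fatigue from
    fused multichannel physiological time series (ECG, EMG, axillary
    temperature, six-channel EEG and eye-tracker signals).  Recordings on a
    common 128 Hz clock are cut into 6 s sliding-window segments with 2 s
    overlap and stacked into channels-by-samples matrices that feed a small
    one-dimensional convolutional network trained against labels derived
    from pre- and post-session Karolinska Sleepiness Scale scores.  The
    package provides a synthetic session generator with a controllable
    latent fatigue trajectory, Monte-Carlo cross-validated training with a
    dynamic learning rate and early stopping, a streaming assessment loop
    that smooths classifier outputs into a continuous fatigue trace, and
    deconvolution-based projection of kernel activations back to the input
    domain for model introspection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
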