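Package: stecg
Title: Stopping-Time Delineation of ECG Waveforms and ST-Elevation
    Myocardial Infarction Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates heartbeat landmarks (R peak, S point, J point, T wave)
    on single-lead electrocardiograms by stopping-time decisions over a
    windowed "downhill U-turn" score, bookkept as action values, softmax
    policies and updated state values. Approximates the isoelectric baseline
    from a pre-R backward search with a weight-adjustment sweep, evaluates
    ST-segment elevation against lead-, sex- and age-specific thresholds,
    derives a STEMI verdict and a right-ventricle-infarction contraindication
    flag, and decides overall waveform inversion by arbitrating a
    least-first-power T-direction stage against an approximate-entropy stage.
    Ships a seeded synthetic ECG generator with ground-truth landmarks, CSV
    and WFDB readers, a JSON report writer and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
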