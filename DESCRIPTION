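Package: physiostress
Title: Budget-Constrained Stress Classification from ECG and Thoracic
    Bioimpedance Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Signal-processing and machine-learning pipeline for assessing
    activity, emotional and mental stress states from two wearable channels:
    a 250 Hz electrocardiogram (ECG) and a 100 Hz thoracic electrical
    bioimpedance (TEB) stream. Multirate FIR/IFIR filterbanks derive eight
    intermediate-frequency physiological signals (slow component, respiration
    rate and depth, pulse rate per channel); a catalog of 112 statistical
    window features is costed with an explicit operations-per-second model;
    feature subsets are selected under a computational budget with a genetic
    algorithm; and linear plus small multilayer-perceptron classifiers are
    evaluated under leave-one-subject-out cross-validation. A seeded synthetic
    cohort generator with known ground-truth heart and respiration dynamics
    makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
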