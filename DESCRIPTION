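Package: emgforce
Title: Muscle Force Estimation from Surface EMG with Hammerstein-Wiener Multimodels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates grip force from surface electromyography (EMG) using a
    library of Hammerstein-Wiener sub-models identified by recursive least
    squares and combined at each time step by residue-based validity weights
    into fused multiple-input multiple-output force estimates. Includes the
    standard EMG preprocessing chain (rectification, 6th-order 1 Hz Butterworth
    envelope, min-max normalisation), a data-driven rule for choosing the
    number of sub-models from EMG envelope statistics, a Levenberg-Marquardt
    multilayer-perceptron baseline, three train/test validation scenarios, and
    a seeded synthetic EMG/force generator emulating a grip-force experiment
    with five force profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    cluster,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
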