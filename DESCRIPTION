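Package: dibhtrack
Title: Stability and Reproducibility Analysis of Spirometer-Guided Deep
    Inspiration Breath Holds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of external-surface position
    reproducibility during spirometer-guided deep-inspiration breath holds
    (DIBH) in left-breast radiotherapy, based on optical tracking of passive
    surface markers. Computes intra-DIBH stability, intrafraction and
    interfraction reproducibility as 5th-95th percentile ranges of marker
    coordinates, free-breathing baselines and their stability, and
    volume-displacement correlation; estimates rigid planning-to-treatment
    transforms with residual displacements, worst-session selection and
    population (group mean / systematic / random) error decomposition;
    performs DLT stereo-camera calibration and triangulation with a
    grid-phantom fixture; and includes a spirometric breath-hold simulator
    that generates multi-session marker-trajectory cohorts with known ground
    truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
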