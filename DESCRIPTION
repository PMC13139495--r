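Package: songrules
Title: Sensorimotor Rules of Drosophila Courtship Song Patterning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for two-fly courtship experiments: kinematic
    feedback features from pose tracks, interaction and quadrant annotation,
    song signal statistics (pulse carrier, width, inter-pulse intervals, bout
    structure, pulse-type clustering), an input-driven hidden-state multinomial
    regression model (HMM-GLM) of song-mode patterning with forward-backward
    inference and EM fitting, behavioural-map embedding with density watershed
    segmentation, and a synthetic-data generator with known ground truth so
    every stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071,
    uwot,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
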