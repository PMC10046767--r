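Package: pausekit
Title: Speech Pause Encoding and Acoustic Ensemble Classification for
    Dementia Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@pausekit.org",
           role = c("aut", "cre"))
Description: Extracts silent-pause structure from spontaneous speech and uses
    it as a digital biomarker for Alzheimer's disease screening. Implements a
    six-sub-band Gaussian-mixture voice activity detector that encodes a
    recording into a binary voiced/non-voiced frame sequence (the VAD Pause
    feature), fixed-length segmentation, segment-level classification with
    five classic machine-learning models, subject-level majority voting and a
    cross-feature-stream ensemble vote, together with confusion-matrix
    metrics and a two-way (feature x classifier) analysis of variance.
    Includes functional acoustic feature profiles sized to the ComParE 2013
    and eGeMAPS standards, WAV input/output, and a synthetic two-group
    speech-corpus generator so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    car,
    class,
    e1071,
    ggplot2,
    jsonlite,
    randomForest,
    rpart,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
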