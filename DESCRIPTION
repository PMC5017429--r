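Package: contextmine
Title: Multimodal Context Mining from Wearable and Ambient Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for inferring human context at two levels
    of abstraction from heterogeneous sensor streams. Low-level contexts --
    physical activities from smartphone/smartwatch inertial windows (k-nearest
    neighbours) and depth-camera skeleton windows (decision tree), emotions
    from phone-call audio (RBF support vector machine on energy, pitch and
    MFCC descriptors), and locations from GPS fixes matched against personal
    place maps -- are fused by vertical (within-recognizer) and horizontal
    (weighted majority voting) unification and emitted as change-only
    notifications. High-level contexts (Inactivity, OfficeWork, Exercising,
    HavingMeal, Housework) are built from concurrent low-level contexts and
    classified against a configurable definitional model. Includes a synthetic
    multimodal data generator, leave-one-subject-out evaluation with confusion
    matrices and F-scores, and an online scenario replay harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
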