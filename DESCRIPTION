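Package: suckletag
Title: Detecting Whale-Calf Suckling from Accelerometer and Depth Tag Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterizing and automatically detecting suckling
    behavior in humpback whale calves from animal-borne tag data (triaxial
    accelerometer plus depth sensor). Derives 10 Hz kinematic channels (depth
    rate, jiggle-calibrated speed, fluke stroke rate, ODBA, pitch, roll, roll
    rate), segments dives into descent/bottom/ascent phases, summarizes
    annotated behavioral events and reference non-suckling segments, builds
    2-second feature blocks (43 statistical features), and detects suckling
    blocks with a natively implemented AdaBoost.M1 classifier evaluated by
    repeated stratified holdout, leave-one-individual-out splits, and
    random-forest Gini-importance feature pruning. Ships a synthetic
    deployment generator with known ground truth so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    jsonlite
Config/testthat/edition: 3
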