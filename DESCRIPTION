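Package: hemamorph
Title: Blood Smear Morphometry and Cell Anomaly Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for automated blood cell analysis on
    microscopy smears: synthetic smear generation with pixel-exact ground
    truth, instance detection with a pluggable detector and a classical
    watershed baseline, a 50-descriptor morphometric feature registry, a
    geometric rule engine classifying erythrocytes into 15 shape categories
    (poikilocytosis screening) and flagging leukocyte anomalies, attribute
    based zero-shot subclass scoring, virtual-staining training objectives,
    a feature-table classifier harness with outlier filtering and k-means
    discretization, and a stratified cross-validation / paired-testing
    evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    MASS,
    class,
    rpart,
    nnet,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
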