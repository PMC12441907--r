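Package: grnlearn
Title: Supervised Gene Regulatory Network Prediction from Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Supervised prediction of transcription factor (TF) to target
    regulatory relationships from gene-by-sample expression compendia.
    Builds labeled TF-target expression-pair datasets (curated positives,
    exclusion-based negative sampling, cross-species label transfer through
    homolog maps), performs TMM normalization of raw count compendia, trains
    fully connected and convolutional neural networks (implemented in base R
    with eight selectable loss functions and an RMSprop optimizer) as well as
    nine classical classifier families, supports hybrid models in which a
    trained convolutional encoder feeds flattened activations to a classical
    classifier, transfers convolutional weights across species with frozen or
    fine-tuned training, evaluates predictions with confusion-matrix metrics
    and ROC/AUC, and prioritizes candidate pathway regulators by their
    frequency among the top-k scored TF-pathway pairs. A seeded synthetic-data
    module generates expression compendia with planted regulatory structure,
    including homolog-linked two-species datasets, so every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    randomForest,
    ranger,
    e1071,
    rpart,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    pROC,
    optparse
Config/testthat/edition: 3
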