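Package: spdcnn
Title: Cross-Subject EEG Classification with Spatial Covariance
    Descriptors and Meta-Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms multichannel EEG trials into normalized spatial
    covariance (symmetric positive semidefinite) descriptors and classifies
    them with a small plain convolutional network.  The network is trained
    for cross-subject few-shot transfer by a three-phase meta-transfer
    learning procedure: joint pre-training on pooled source subjects,
    episodic meta-learning of per-layer scaling-and-shifting parameters over
    subject-specific N-way K-shot tasks, and few-shot fine-tuning of the
    classifier head for a new user with the feature extractor frozen.
    Includes a multi-subject synthetic EEG generator whose class signal
    lives in the spatial covariance and whose subject identity induces a
    controllable domain shift, plus evaluation utilities (cross-subject
    folds, accuracy aggregation, and a PCA-based inter-subject distance
    analysis of raw versus covariance representations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
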