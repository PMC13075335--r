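Package: equibehave
Title: Hierarchical Cost-Sensitive Classification of Horse-Human Interaction Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated recognition of horse-human interaction behavior from
    per-frame detection and keypoint streams. Implements a six-leaf / three-parent
    behavioral taxonomy with ethogram consolidation, a BORIS-style annotation event
    reader with temporal sampling, a synthetic dyadic interaction simulator, a
    35-dimensional multi-modal feature extractor (spatial, human pose, equine pose),
    robust median/IQR scaling with missing-value imputation, cost-sensitive class
    weighting, a two-stage hierarchical gradient-boosted classifier with oracle and
    cascaded routing, stratified/grouped/leave-one-video-out cross-validation,
    statistical validation utilities (Wilson intervals, McNemar, paired fold tests,
    Cohen's kappa, one-vs-rest ROC/PR), and robustness analyses (modality ablation,
    keypoint perturbation, landmark dropout, temporal majority-vote smoothing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    pROC,
    e1071
Config/testthat/edition: 3
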