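Package: motistate
Title: Motivation-State Fluctuations and Learning in Head-Fixed Go/No-Go Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for motivation-state fluctuations and learning in
    head-fixed go/no-go whisker training. Labels every trial as persistent,
    disengaged or attentive from smoothed licking and correctness; predicts the
    states from eight nonperformance variables (prestimulus licking, wheel
    speed, pupil diameter, eyelid aperture, aperiodic power-spectrum slope,
    evoked LFP, prestimulus multiunit power, evoked multiunit activity) with
    bagged decision trees, pooled ROC curves and an asymptotic-exponential fit
    of AUC versus predictor-pool size; maps trial subcategories onto a
    99-block normalized training-progression axis with repeated-measures
    ANOVA of peristimulus motor patterns; and profiles laminar
    current-source-density and multiunit responses along cortical depth. A
    fully parameterized synthetic-data generator emulates multi-mouse,
    multi-session recordings (trial tables, lick events, wheel encoder, eye
    keypoints, laminar LFP and high-rate epochs) so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    nnet,
    minpack.lm,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
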