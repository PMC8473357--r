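Package: gaitfusion
Title: Locomotion Mode Recognition and Prediction from Fused sEMG and
    Acceleration Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Online recognition and prediction of human locomotion modes
    (sit, stand, level walk, stair and ramp ascent/descent) from fused
    surface electromyography (sEMG) and lower-limb linear acceleration
    signals.  Provides a seedable synthetic gait-trial generator in which
    muscle activation leads the kinematic change at each mode transition,
    zero-lag Butterworth preprocessing, coordinate-based heel-strike
    detection and gait-cycle segmentation, sliding-window RMS feature
    fusion, four classifier harnesses (SVM, KNN, LDA, ANN), a streaming
    decision layer combining an agreement vote with a transition-legality
    rule table, and evaluation of classification accuracy, sensitivity,
    specificity, predictive accuracy and response time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    e1071,
    class,
    MASS,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
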