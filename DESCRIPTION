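Package: mdcleanse
Title: Two-Stage Mahalanobis-Distance Data Cleansing for Wearable
    Accelerometer Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multivariate data cleansing for triaxial accelerometer
    human-activity-recognition (HAR) datasets.  Recordings are segmented
    into non-overlapping time windows, 51 time- and energy-domain
    features are extracted per window, and windows are screened in two
    stages by their Mahalanobis distance from the within-group mean,
    flagging observations whose squared distance exceeds a chi-square
    quantile.  The package also provides correlation-based feature
    subset selection with best-first search, KNN and random-forest
    evaluation harnesses with repeated train/test splits and 10-fold
    cross-validation, statistical comparison of classifier F-measures
    (Anderson-Darling normality checks, Welch t-tests, one-way ANOVA),
    and a synthetic-data generator that emulates multi-subject,
    multi-activity accelerometer recordings with controllable
    contamination so the cleansing method can be studied end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    class,
    randomForest,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
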