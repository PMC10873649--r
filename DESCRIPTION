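Package: fairuad
Title: Fairness Auditing for Unsupervised Anomaly Detection with Subgroup-AUROC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to audit the fairness of unsupervised anomaly detection
    models from their anomaly scores alone. Implements the subgroup-AUROC
    (sAUROC), a threshold-free metric that traces population-level true
    positive rate against subgroup-level false positive rate, together with
    its thresholded companion, the subgroup false positive rate at a minimum
    population-wide true positive rate. Provides composition-controlled,
    patient-disjoint dataset splitting with prevalence correction; fitting and
    interpolation of empirical "fairness laws" (linear relationships between a
    subgroup's training representation and its sAUROC); Welch tests for
    disparities under balanced training data; intersectional disparity
    reports; and a synthetic anomaly-score generator with a linear
    representation-shift mechanism so the full workflow runs without imaging
    data or model training. A command-line interface covers the simulate,
    split, evaluate, laws and intersect steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
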