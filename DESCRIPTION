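Package: equigait
Title: Pose-Estimation-Based Lameness Analysis for Lunged Horses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses markerless pose-estimation keypoint trajectories of
    horses trotting on left and right lunging circles to detect and
    lateralise forelimb and hindlimb lameness. Reads DeepLabCut-style CSV
    trajectory tables, applies likelihood-based frame exclusion and
    percentile-band trimmed excursion statistics, segments strides from
    limb protraction maxima, quantifies stance-synchronous head-nod
    asymmetry for the forelimbs and circle-difference excursion scores for
    the stifle and tuber coxae, and evaluates classifications against
    clinical ground truth with sensitivity, specificity, predictive values,
    Cohen's kappa and overall accuracy. A synthetic trot-trajectory
    generator provides reproducible test cohorts with controlled lameness
    asymmetries and likelihood dropouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    graphics
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
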