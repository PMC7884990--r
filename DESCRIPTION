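Package: sparenet
Title: Structural Connectome Abnormality Mapping and Epilepsy Surgery
    Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies structural brain-network abnormality in epilepsy
    surgery candidates by z-scoring patient connectome edges against a
    normative control cohort, constructs the surgically spared subnetwork
    implied by a planned resection, counts abnormal nodes over a
    two-dimensional (z, percentage) threshold grid, summarizes where surgery
    reduces abnormality across ipsilateral and contralateral brain areas, and
    predicts post-surgical seizure outcome and relapse likelihood with a
    nested leave-one-out linear support-vector classifier with recursive
    feature elimination. Includes a synthetic cohort generator with planted
    abnormal subnetworks so the whole pipeline is testable with known ground
    truth, plus the statistical toolkit used throughout: exact Wilcoxon
    rank-sum, Cohen's d, BCa bootstrap confidence intervals,
    Benjamini-Hochberg FDR, Spearman correlation, and a permutation test of a
    robust regression slope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
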