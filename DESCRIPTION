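Package: daybiome
Title: Matched-Design Longitudinal Analysis of Day-Care Effects on the
    Early-Childhood Gut Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing longitudinal 16S ASV feature tables from
    cohorts of children entering day care, with age-matched home-care
    controls. Implements binary Jaccard, Bray-Curtis and unweighted UniFrac
    beta diversity with principal coordinates analysis; per-timepoint
    age-matched pair construction and greedy home-care-anchor matching;
    a paired rank-mean permutation test for differential abundance with
    discrete false-discovery-rate (dsFDR) control; sequential PERMANOVA
    variance partitioning with subject strata; a slope-equality permutation
    test for alpha-diversity trajectories; a matched-subset random-forest
    classification protocol with out-of-bag ROC AUC and Youden thresholds;
    and a synthetic longitudinal cohort generator with planted ground truth
    so every stage can be exercised without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    randomForest,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
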