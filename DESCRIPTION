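Package: sirnaml
Title: Trichotomous Threshold Models for Chemically Modified siRNA Efficacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification framework for predicting the silencing efficacy of
    chemically modified small interfering RNAs (siRNAs) from their 20-nt mRNA
    target-site sequence. Implements trichotomous two-threshold class labeling
    swept over all equal-count threshold pairs, random-forest and linear
    base-frequency-difference classifiers behind a common train/score contract,
    an adjusted precision-recall area (AUCPRadj) that removes the prevalence
    floor so models built at different effective thresholds are comparable,
    model-agnostic proxy extraction of position-base weight matrices,
    label-shuffle controls, transcript scanning for siRNA candidate ranking,
    and a seeded synthetic-data generator with planted position-base effects
    so every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
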