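Package: amrgrade
Title: Multi-Platform Chemometric Grading of Atractylodis Macrocephalae Rhizoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-dimensional quality grading of Atractylodis
    Macrocephalae Rhizoma (AMR, baizhu). Implements fuzzy-mathematics sensory
    scoring from evaluator panels, orthogonal partial least squares
    discriminant analysis (OPLS-DA) with VIP-based differential screening and
    permutation validation, sensor-array screening for electronic-nose and
    electronic-tongue data with sensor-compound Spearman correlation mapping,
    and mid-level data fusion of four measurement platforms into KNN, BPNN and
    random-forest grade classifiers. Ships a seeded synthetic-data generator
    that emulates the four platforms and the four-grade batch structure so the
    whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
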