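Package: lifelipid
Title: Lipidome Signatures of Mammalian Maximal Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline linking mammalian maximal lifespan (MLS) to
    tissue lipidome composition. Covers internal-standard normalization and
    quality filtering of untargeted lipidomics peak tables, adduct-based
    compound annotation and correlated-peak merging, removal of lipids
    associated with confounding factors (sex, age, diet, hibernation, basal
    metabolic rate, body mass and temperature) with permutation-based
    family-wise error control, elastic-net logistic classification of
    long-living species with repeated cross-validation, a clade-elimination
    robustness protocol, lipid-class enrichment and concentration-shift
    statistics for the selected predictors, and comparison of dN/dS ratios
    of enzymes linked to predictor lipids. A synthetic-data generator
    emulates the statistical structure of a multi-clade, multi-tissue
    mammalian cohort with planted lifespan-associated signal, providing
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
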