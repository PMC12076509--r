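Package: porphgeom
Title: Structural Aromaticity, Nonplanarity and Steric Descriptors for Metalloporphyrins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for geometric analysis of metalloporphyrin crystal
    structures: parsing CIF/XYZ files, distance-based bond perception,
    seven-rule structure curation, detection of the porphyrin macrocycle and
    canonical atom-role assignment, HOMA/EN/GEO structural-aromaticity scores
    on the inner-cross and pyrrole circuits, normal-coordinate structural
    decomposition of out-of-plane distortion (saddling, ruffling, doming,
    waving, propellering), substituent steric descriptors (minimal enclosing
    cone angles and surrogate-frame crowding distances), and interpretable
    LASSO / random-forest structure-property models with an
    unseen-substituent train/test protocol. A synthetic-geometry generator
    produces distorted porphyrin populations with a planted linear
    structure-property law for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    igraph,
    glmnet,
    randomForest,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
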