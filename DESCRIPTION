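Package: driverscan
Title: Combined Burden and Functional-Impact Discovery of Cancer Driver Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers candidate cancer driver elements from somatic mutation
    catalogs by modelling the background mutation rate (BMR) of genomic
    elements from covariate features, testing elements for excess mutational
    burden against a binomial or negative-binomial null, and up-weighting
    elements whose mutations carry high predicted functional impact. Provides
    interval arithmetic for masked genomic elements, per-element feature
    construction (nucleotide content, track signal, peak overlap), robust
    feature scaling, stability-selection feature ranking with a randomised
    lasso, binomial GLM and gradient-boosted Poisson BMR models, a
    regression-based overdispersion test, phred-scaled functional impact
    aggregation, Benjamini-Hochberg correction at cohort and global scope,
    a benchmarking protocol against reference driver lists, and a synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    xgboost,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    methods,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
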