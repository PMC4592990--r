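Package: tagging
Title: Thinning and Aggregating Ensemble Learning for QTL Mapping and
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the TAGGING (thinning and aggregating) framework for
    ensemble learning of quantitative trait locus (QTL) models in multi-family
    recombinant inbred line (RIL) panels such as nested association mapping
    (NAM) designs. A dense linkage map is partitioned into disjoint thinned
    sub-maps, stepwise multiple-regression QTL models (single-family or
    joint-family with family-specific allele effects) are fitted to each
    sub-map as independent base learners, and their predictions are averaged.
    Companion tools provide VanRaden realized genomic relationship matrices
    and GBLUP prediction, subsample-aggregation (subagging) comparators,
    stratified cross-validation with within-family prediction R-squared,
    bias-variance decomposition of prediction error, resample model inclusion
    probabilities (RMIP), equal-weight and Nelder-Mead-optimized model
    averaging across heterogeneous predictors, and a synthetic multi-family
    RIL simulator with known QTL architecture for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
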