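Package: grepredict
Title: Gene Ratio Expression Prediction of Drug Sensitivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds drug-response classifiers from pairwise gene-expression
    ratios (GREP: Gene Ratio Expression Prediction). Provides screen
    processing (sigmoidal dose-response fits, Amax/EC50/IC50 extraction,
    three-class sensitivity calls and majority-vote consensus, lineage
    enrichment, xenograft %T/C and %Regression response calls), expression
    preparation (probe collapse, expression-level and dynamic-range gene
    filters), pairwise log-ratio features with permutation-based p- and
    q-values, affinity propagation exemplar clustering, ridge-penalized
    logistic classification under stratified cross-validation, baseline
    comparators and ablations, ratio-network and gene-elimination
    interpretation, and a synthetic-data generator with planted ratio
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
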