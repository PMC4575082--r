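Package: structscan
Title: Marker-Set Design and Bayesian Structure Inference for SSR
    Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate how microsatellite (SSR) marker-set size and
    marker-selection criterion affect Bayesian inference of genetic structure
    in germplasm collections. Implements fingerprinting statistics
    (discrimination power, banding patterns, cumulative discrimination),
    linkage-group-aware marker ordering, a Structure-type Gibbs sampler for
    multi-allelic codominant genotypes of mixed ploidy (diploid and triploid)
    with optional prior-population flags, Evanno delta-K model selection over
    replicate runs with exact label alignment, cross-analysis assignment
    stability indices, ploidy-aware Weir-Cockerham F_ST with permutation
    tests, nested subgrouping pipelines, and an F-model simulator of SSR
    collections with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
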