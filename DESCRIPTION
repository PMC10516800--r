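Package: metaconn
Title: Cross-Subject Metabolic Connectivity Analysis of Brain Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-subject (inter-animal) metabolic connectivity
    analysis of regional brain-activity data, as used with autoradiographic
    2-deoxyglucose uptake measurements. Computes within-group inter-regional
    Pearson correlation matrices with Fisher r-to-z transforms, applies a
    leave-one-subject-out jackknife reliability criterion to individual
    correlations, tests between-group differences in correlation coefficients
    with a Fisher Z-test protected by a 2n-iteration double jackknife,
    summarises networks as signed connectivity densities per structure pair,
    and performs graph-theoretic degree and hub analysis with a Kamada-Kawai
    layout. Ships a 176-region cortico-basal ganglia-thalamic parcellation
    and a synthetic multivariate-normal data generator with block covariance
    and plantable edge effects so the whole pipeline can be exercised against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
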