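Package: tpodmix
Title: Transcriptomic Points of Departure for Chemical Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Concentration-response analysis of targeted transcriptomic
    count data for mixture risk assessment: cytotoxicity (LDH) and
    sample quality-control gates, median-of-ratios library-size
    normalization with vehicle-matched rescaling, Williams-type trend
    prefiltering with permutation p-values, benchmark concentration (BMC)
    modeling over the standard dose-response model suite with bootstrap
    resampling and profile-likelihood confidence bounds, transcriptomic
    points of departure (25th gene BMC and lowest pathway median BMC)
    with percentile confidence intervals from simulated experiments, and
    concentration-addition prediction of mixture potency via relative
    potency factors. A synthetic-data generator with analytic
    ground-truth BMCs supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'simulate.R'
    'qc.R'
    'normalize.R'
    'trend.R'
    'bmc-models.R'
    'bmc-profile.R'
    'bmc-bootstrap.R'
    'tpod.R'
    'mixture.R'
    'io.R'
    'pipeline.R'
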