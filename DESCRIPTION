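Package: methMWAS
Title: Mixed-Model Methylome-Wide Association Analysis of Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for blood methylome-wide association studies of binary
    disease status. Implements probe- and sample-level quality control for
    Illumina-style beta-value matrices, reference-based blood cell-type
    deconvolution, the omics relationship matrix and restricted maximum
    likelihood estimation of the phenotypic variance captured jointly by all
    methylation probes, mixed-linear-model association scans in which the
    tested probe is fitted as both a fixed and a random effect (with a
    multi-component variant that excludes probes near the target), fixed-effect
    inverse-variance meta-analysis and replication diagnostics, summary-data
    Mendelian randomization with a heterogeneity-in-dependent-instruments
    test, and BLUP-based methylation profile scoring with out-of-sample
    classifier evaluation. A synthetic-cohort generator with known truth
    supports calibration and power studies without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    pracma,
    pROC,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
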