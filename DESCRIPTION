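Package: tnbcsig
Title: Multi-Protein Survival Signatures for Triple-Negative Breast
    Cancer Proteomics
Version: 0.1.0
Authors@R:
    person("Marta", "Ruiz", email = "marta.ruiz@example.org",
           role = c("aut", "cre"))
Description: Discovery and cross-platform validation of multi-protein
    prognostic signatures from label-free quantitative proteomics of
    triple-negative breast cancer. Implements the full pipeline:
    quantifiable-protein filtering, outlier-sample exclusion, log2
    transformation, downshifted-Gaussian imputation of left-censored
    missing values, z-scoring and empirical-Bayes (ComBat-style) batch
    correction; per-protein univariate Cox screening against distant
    metastasis-free survival; correlation-group construction and random
    reduced-profile sampling; supervised principal-component risk
    scoring with a-priori rank-quantile cutoffs; leave-one-out
    cross-validation and permutation log-rank testing; and application
    of frozen signature models to parallel-reaction-monitoring
    light/heavy ratio data and probe-level transcriptomics. A synthetic
    cohort generator with planted prognostic structure makes every
    stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
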