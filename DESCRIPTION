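Package: csfATpipe
Title: Multi-Stage CSF Aptamer Proteomics Analysis Across the AT Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for cerebrospinal-fluid (CSF) aptamer
    proteomics studies of the Alzheimer's disease continuum. Provides quality
    control of relative-fluorescence-unit (RFU) matrices (scale-factor,
    coefficient-of-variation and interquartile-range rules), Gaussian-mixture
    dichotomization of amyloid and tau biomarkers into AT groups, per-analyte
    covariate-adjusted differential abundance with surrogate variables, a
    three-stage discovery/replication/meta-analysis design using Stouffer's Z,
    sparse protein-signature derivation (lasso selection, correlation pruning,
    platform restriction, multivariate refit) with frozen-model evaluation,
    pseudo-trajectory grouping of proteins across disease stages, Boolean
    pruning of signed regulatory networks with elementary-circuit enumeration
    and hypergeometric enrichment, and clinical-outcome models (progression
    slopes and Kaplan-Meier time-to-conversion). A multi-cohort synthetic data
    generator with planted ground truth makes every stage testable without
    access to private cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
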