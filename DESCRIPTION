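Package: mrflow
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization workflow for GWAS
    summary statistics: instrument selection (genome-wide significance
    filtering, greedy LD clumping against a user-supplied r-squared matrix,
    palindromic-variant removal, Steiger directionality filtering), allele
    harmonization between exposure and outcome studies, causal estimation
    (Wald ratio, multiplicative random-effects inverse-variance weighting,
    MR-Egger regression, weighted median with parametric-bootstrap standard
    errors), and sensitivity analysis (Cochran's Q, MR-PRESSO global/outlier/
    distortion tests, leave-one-out). Includes a synthetic summary-statistics
    generator with planted causal effects, configurable pleiotropy and
    block-structured linkage disequilibrium, so every pipeline stage can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'estimators.R'
    'instruments.R'
    'mrflow-package.R'
    'synthetic.R'
    'sensitivity.R'
    'pipeline.R'
    'sumstats-io.R'
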