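Package: cnvdose
Title: Dosage Effects of Recurrent Copy Number Variants on Height and BMI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A federated analysis toolkit for estimating gene-dosage effects
    of recurrent copy number variants (CNVs) on anthropometric traits.
    Assigns locus-level CNV genotypes from raw interval calls against a
    segmented recurrent-locus catalog, harmonizes trait scaling
    (residualization, per-sex Box-Cox, pediatric LMS z-scores), fits
    per-cohort association and interaction models, pools cohorts by
    inverse-variance fixed-effects meta-analysis (coefficients and Fisher-
    transformed variance explained), decomposes deletion/duplication
    dose-response curves into linear components, tests sex differences,
    age-dependent growth trajectories and BMI-mediated effects, and tests
    additivity of breakpoint subregions. Includes a synthetic multi-cohort
    data generator with known truth for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    MASS,
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
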