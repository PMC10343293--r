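Package: pkunmr
Title: Urinary 1H-NMR Metabolomics of Phenylketonuria: Simulation,
    Binning, Classification and Targeted Statistics
Version: 0.1.0
Authors@R:
    person("PKU", "NMR Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for case/control urinary 1H-NMR
    metabolomics of phenylketonuria (PKU). Provides a calibrated synthetic
    cohort generator (concentration tables in mmol/mol creatinine, patient
    metadata, Lorentzian-peak spectra), creatinine-scaled fixed-width
    spectral binning with water-region exclusion, an untargeted
    PCA/canonical-analysis/k-nearest-neighbour classifier validated by
    Monte-Carlo embedded cross-validation, a targeted Mann-Whitney and
    fold-change screen with limit-of-detection filtering, standardized
    multifactorial regression, and genotype/phenotype-value based
    patient stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
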