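Package: twinliab
Title: Liability-Threshold Twin Models for Ordinal Depression Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for classical twin studies of ordinal (liability
    threshold) phenotypes such as minor and major depression. Provides a
    synthetic twin-cohort generator under the bivariate-normal liability model
    with ACE/ADE variance components and linear age and sex threshold effects;
    DSM-IV symptom-count classification; proband to co-twin relative risks with
    confidence intervals; maximum-likelihood polychoric and tetrachoric
    correlations with the multiple-threshold (single liability continuum)
    chi-squared goodness-of-fit test; full-ML univariate ordinal twin
    structural-equation models (ACE, ADE, AE, CE, E) with likelihood-ratio
    tests, AIC and profile-likelihood confidence intervals; and a Monte-Carlo
    power study of broadened (subthreshold-inclusive) case definitions in
    case-control association testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
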