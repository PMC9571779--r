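Package: mixqsar
Title: QSAR Models for the Aquatic Toxicity of Binary Chemical Mixtures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modelling of
    the aquatic toxicity (pEC50) of binary chemical mixtures from hypothetical
    mixture descriptors.  Provides eleven mixing rules that combine two
    components' molecular descriptors with their toxic-unit composition into
    mixture descriptors, descriptor screening and forward stepwise multiple
    linear regression, a radial basis function neural network regressor with
    forward subset centre selection and width grid search, a validation suite
    (R-squared, RMS, F, MAE, leave-one-out Q2, external q2, slope through the
    origin, Y-randomization, blocked five-fold cross-validation), Williams-plot
    applicability-domain analysis, packaged toxicity tables for 35 individual
    compounds and 79 binary mixtures, and a synthetic-data generator emulating
    the correlated five-descriptor design of the study system.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
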