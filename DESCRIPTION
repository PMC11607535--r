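Package: cascadebias
Title: Cross-Sectional Sampling Artifacts in Biomarker Cascade Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate the Alzheimer's disease biomarker cascade as a
    linear inhomogeneous ODE system with a nilpotent coupling matrix, solved in
    closed form, plus an optional nonlinear cognitive-reserve extension
    integrated with Dormand-Prince. Generates synthetic longitudinal cohorts,
    applies consistent, random and time-residualized cross-sectional sampling,
    and runs repeated standardized interaction regressions to quantify how
    cross-sectional sampling manufactures faux moderation effects between
    pathology biomarkers and candidate cognitive-reserve surrogates, and how
    partialling out (possibly noisy) sampling time suppresses them. Includes
    recovery of the cascade parameters from longitudinal panels via nested
    linear mixed-effects model families selected by conditional AIC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lme4,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
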