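Package: cgpfield
Title: Field-Trial Simulation and Techno-Economic Analysis of Plant-Made
    Cyanophycin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for evaluating cyanophycin granular polypeptide (CGP)
    production in field-grown tobacco as a biopolymer coproduct. Provides a
    synthetic-data generator emulating a randomized-block field trial with
    Mendelian 1:2:1 transgene segregation; size-exclusion-chromatography
    quantification via linear calibration and trapezoidal peak integration;
    integration-locus and zygosity classification from antibiotic-resistance
    germination counts; staged extraction mass-balance accounting; a
    deterministic scenario table plus a 100,000-repetition Monte Carlo
    techno-economic model over triangular distributions; and a hierarchical
    Bayesian multinomial-logit estimator for choice-based conjoint data,
    validated by parameter recovery on synthetic choices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    car,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
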