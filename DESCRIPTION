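Package: cilitox
Title: Mixture Ecotoxicology Analysis for Ciliate Acute Bioassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for acute metal and nanoparticle mixture
    toxicity bioassays with unicellular organisms. Fits two-parameter
    logit-log concentration-response curves and estimates LCx values with
    delta-method confidence intervals; builds Toxic Unit (TU) mixture
    designs and classifies interactions by effect summation; fits
    Concentration Addition (CA) and Independent Action (IA) response
    surfaces with synergism/antagonism, dose-ratio and dose-level
    deviation functions selected by chi-squared likelihood-ratio tests;
    and runs the standard statistical battery (Shapiro-Wilk, Levene,
    one-way ANOVA with Bonferroni post hoc, Pearson correlation) on
    sublethal antioxidant biomarker panels. Includes seeded synthetic-data
    generators matching the microwell assay design for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    car,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
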