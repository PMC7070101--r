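Package: ehckin
Title: Individual Kinetic Modeling of Postprandial Plasma Bile Acid Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic compartmental modeling of the human enterohepatic
    circulation of bile acids, fitted per subject to plasma concentration
    time series from repeated mixed-meal tests. Provides an ordinary
    differential equation model of hepatic synthesis and conjugation,
    gallbladder storage and meal-triggered emptying, intestinal transit,
    active and passive uptake, microbial deconjugation and dehydroxylation,
    and hepatic first-pass extraction with plasma spillover; a synthetic
    mixed-meal-test cohort generator with known ground truth; descriptive
    variability statistics (AUC, incremental AUC, peaks, inter- and
    intraindividual coefficients of variation); multi-start L1 parameter
    estimation; practical identifiability classification from restart
    ensembles; and local sensitivity ranking of model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
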