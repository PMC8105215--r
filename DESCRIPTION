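Package: clavpk
Title: Validation and Pharmacokinetics of Clavulanic Acid LC-MS/MS Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative workflow for targeted LC-MS/MS determination of
    clavulanic acid in broiler chicken plasma and meat: monoisotopic mass and
    ppm mass-accuracy calculation with identity confirmation, weighted (1/x)
    linear calibration with LOD/LOQ estimation per EU guidance, bioanalytical
    method validation (recovery, within-run precision, specificity, storage
    stability) against VICH GL49 / 2002/657/EC acceptance rules, and
    non-compartmental pharmacokinetic analysis (Cmax/Tmax, terminal
    elimination rate, half-life, trapezoidal AUC with exponential tail) of
    destructive-sampling group-mean profiles. Includes a seeded synthetic
    data generator that emulates the statistical structure of every input
    the pipeline consumes, so the full workflow runs end to end without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
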