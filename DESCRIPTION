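Package: sedem
Title: SeDeM Expert System for Powder Characterization and
    Direct-Compression Suitability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts raw powder-characterization measurements of a drug
    substance (bulk/tapped volumes, tablet hardness, angle of repose, flow
    time, loss on drying, hygroscopicity, sieve analysis, laser-diffraction
    particle-size curves) into the twelve SeDeM parameters, their 0-10
    radius profile and radar diagram, and the compressibility indices
    (parametric index IP, parametric profile IPP, good-compression index
    GCI).  Adds the batch-statistics layer used in manufacturing process
    validation: per-parameter descriptive statistics, Levene variance
    checks and one-way ANOVA for batch reproducibility, pilot-to-industrial
    scale transposition, and supplier comparison.  Includes reference
    radius tables for a three-supplier Linezolid study, a seeded synthetic
    supplier/batch generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
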