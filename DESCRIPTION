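Package: lipidfast
Title: Whole-Body Hepatic Lipid Metabolism Kinetics and Fourier Amplitude
    Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kinetic simulation of a four-compartment (liver, skeletal
    muscle, adipose tissue, blood plasma) model of glucose, insulin and
    lipid exchange after a meal, together with a non-stationary Fourier
    Amplitude Sensitivity Test (FAST) that quantifies how the model's
    kinetic parameters control metabolite concentrations and reaction
    rates over time.  Includes conversion of menu macronutrient tables
    into initial plasma glucose and triglyceride concentrations, a
    synthetic menu generator spanning ketogenic to general-population
    diets, stiff integration of the 23 balance equations, first-order
    FAST sensitivity indices with percentile-based reporting, and an
    optional SBML export of the reaction network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
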