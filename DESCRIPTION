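Package: carbfix
Title: Integrated In Silico Analysis of Photo-Electro-Autotrophic Pathway Designs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based evaluation of synthetic photo-electro-autotrophic
    designs in the Escherichia coli core metabolic network. Couples six carbon
    fixation pathways (Calvin, reductive TCA, 3-hydroxypropionate-4-hydroxybutyrate,
    dicarboxylate-4-hydroxybutyrate, and two pyruvate-synthase-based synthetic
    bicycles) to a proton-pumping rhodopsin photosystem and a generalized
    extracellular electron uptake system. Provides flux balance and flux
    variability analysis on a built-in simplex solver, ATP accounting per
    biomass precursor, Max-min Driving Force (MDF) thermodynamic pathway
    analysis over metabolite log-concentrations, flux-force efficacy and
    pathway specific activity kinetics, and protein burden estimates, together
    with a synthetic-fixture generator with analytically known optima for
    testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
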