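Package: mfao
Title: Kinetic Modelling and Control Analysis of Mitochondrial Fatty-Acid Beta-Oxidation
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing kinetic models of mitochondrial
    fatty-acid beta-oxidation (mFAO) with promiscuous enzymes. Chain-length
    ladders of CoA esters are converted by a small set of enzymes that each
    accept substrates of several chain lengths, modelled as generalized
    reversible Michaelis-Menten rate laws in which every alternative substrate
    and product acts as a competitive inhibitor. The package provides the
    network constructor for the rat-liver mFAO pathway, a seeded generator of
    synthetic pathway instances, time integration and steady-state solving
    with conserved-moiety reduction, substrate and parameter scans,
    finite-perturbation Metabolic Control Analysis (flux control and response
    coefficients, elasticities, response dissection), time-dependent
    regulation analysis of substrate-upshift transitions, in-silico removal of
    enzyme promiscuity, active-site occupancy calculations, SBML import, and a
    command-line pipeline that emits CSV result bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
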