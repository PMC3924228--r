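Package: crowdfba
Title: Crowding-Constrained Flux Balance Modeling of Carbon Catabolite
    Repression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Flux balance analysis with a macromolecular-crowding budget
    (FBAwMC) on a reduced five-substrate Escherichia coli network, with
    dynamic-FBA batch culture simulation, chemostat steady-state scans
    across dilution rates, and the descriptive kinetics used alongside
    such experiments: log-ratio growth rates from OD600 time courses,
    one-phase-decay fits of biomass-normalized substrate uptake,
    GFP/OD600 promoter activities, and Ficoll density-gradient cell
    density distributions. Includes seeded synthetic-data generators with
    known ground truth for every analysis input, and a brute-force
    vertex-enumeration oracle for validating the linear-programming
    solver on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
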