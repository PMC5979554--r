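Package: hivedock
Title: Hybrid Bee-Colony/Differential-Evolution Search for Protein-Ligand Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Flexible-ligand, rigid-receptor molecular docking driven by a hybrid
    metaheuristic: an artificial bee colony (ABC) and a differential evolution (DE)
    evolver share one population, and an adaptive population-partition controller
    reallocates individuals between them each generation from elite probabilities
    and evolution rates. Poses are scored with a semi-empirical pairwise binding
    free-energy function (dispersion/repulsion, 12-10 hydrogen bonding, screened
    electrostatics, Gaussian desolvation, and a torsional entropy penalty)
    evaluated directly over receptor-ligand atom pairs. Includes a PDBQT
    reader/writer with torsion-tree support, a synthetic toy-complex generator
    with planted poses and brute-force oracles, benchmarking utilities (success
    rates, box-plot statistics, rank tests), and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
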