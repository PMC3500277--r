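Package: ssescore
Title: Knowledge-Based Scoring of Protein Models Reduced to Secondary
    Structure Elements
Version: 0.1.0
Authors@R:
    person("ssescore", "maintainers", email = "ssescore@example.org",
           role = c("aut", "cre"))
Description: Statistical potentials and penalty terms for ranking protein
    models represented only by idealized alpha-helices and beta-strands with
    one side-chain anchor point (C-beta; H-alpha2 for glycine) per residue.
    Implements inverse-Boltzmann training of energy tables from structure
    databases, fragment-based secondary-structure-element packing geometry
    (twist, offset and contact weights), amino acid environment and pair
    distance potentials, loop length, contact order, radius of gyration and
    secondary-structure-prediction agreement scores, clash and loop-closure
    penalties, a weighted consensus score, decoy enrichment statistics with
    balanced cross-validation subsets, and Monte-Carlo simulated-annealing
    weight optimization. Ships a synthetic fixture generator (ideal SSEs,
    toy topologies, perturbation decoys and synthetic secondary-structure
    predictions) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
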