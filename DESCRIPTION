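Package: spcmodel
Title: Multi-Template Protein Model Generation by Stochastic Point Cloud Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates Calpha-trace structural models of a target protein from
    one or more aligned template structures. Superposed template Calpha atoms
    form a weighted point cloud per target residue; residues whose cloud spread
    exceeds 0.5 Angstrom are resampled from a three-dimensional multivariate
    normal distribution under chain-connectivity and clash restraints, with
    candidate models accepted by a simulated-annealing protocol. Unaligned
    regions are built by constrained shell sampling, structurally inconsistent
    template regions are filtered before averaging, and targets whose templates
    fall into disconnected coverage groups are split into domains that are
    modeled separately and rigidly recombined by a moving-rotation search.
    Includes rigid-body superposition, TM-score and GDT-TS utilities, a
    synthetic-data generator for end-to-end testing, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    MASS,
    jsonlite,
    optparse,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
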