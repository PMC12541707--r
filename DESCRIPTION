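Package: nanopep
Title: Evolution-Guided Design and Co-Assembly Analysis of Minimal Peptide
    Drug Nanocarriers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing four-residue peptide nanocarriers that
    co-assemble with small-molecule cancer drugs and Zn2+/NO3- ions.
    Implements a charge-neutrality composition solver, an empirical
    pairwise association free-energy scorer with a separable zinc
    coordination term, Shrake-Rupley solvent-accessible surface area,
    an iterative evolution-guided "lock and design" sequence optimizer
    with consensus ranking across drugs, builders for idealized ordered
    assemblies and random co-assembly snapshots, and a post-processing
    suite for multicomponent cluster detection, encapsulation and
    composition statistics, geometric beta-sheet assignment, drug
    mediation probabilities, and energy-versus-burial profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
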