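Package: shiftsel
Title: Chemical-Shift-Driven Ensemble Selection for Amorphous Molecular Solids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: NMR crystallography analysis for amorphous molecular solids:
    models experimental chemical-shift distributions (Gaussian peak fitting,
    shielding-to-shift referencing, nearest-peak assignment refinement),
    scores candidate molecular environments from molecular-dynamics ensembles
    against those distributions by a geometric-mean p-value, selects the
    best-matching "NMR set", and quantifies which structural motifs
    (hydrogen bonds, dihedral distributions, distances, cluster formation
    energies) are promoted or demoted relative to the full MD ensemble.
    Includes a synthetic-ensemble generator with planted conformational
    ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
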