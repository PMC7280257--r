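Package: ledaffinity
Title: Protein-Ligand Binding Affinity Models from Local Energy
    Decomposition Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Static-structure pipeline for modelling competitive-inhibitor
    binding affinities of Torpedo californica acetylcholinesterase. Extracts
    active-site clusters from protein-ligand crystal structures with an
    any-atom 3.5 Angstrom contact rule, writes two-fragment XYZ and
    coupled-cluster LED input decks, parses local-energy-decomposition
    (LED) output text into five energetic descriptors (inter-fragment
    binding energy, electrostatics, exchange, charge transfer, dispersion,
    all in kcal/mol), and fits multiple-linear-regression models of
    log10(Ki) on those descriptors with percent-sum-of-squares, residual,
    leave-one-out Q2/PRESS, variable-selection, single-variable-exclusion
    and leave-one-point-out commensurability (outlier) statistics. Ships
    the seven-complex acetylcholinesterase reference dataset and synthetic
    generators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
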