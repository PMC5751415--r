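Package: cgbsa
Title: Charge-State Exploration and MM/GBSA Binding-Energy Scoring for
    Kinase Inhibitor Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring ligand charge states and scoring
    protein-ligand binding with a single-trajectory MM/GBSA workflow.
    Converts dissociation constants to standard binding free energies
    with first-order error propagation, enumerates protonation
    microstates of multi-site ionisable ligands from per-site pKa
    values at a given pH, evaluates molecular-mechanics plus
    Generalized Born (OBC) plus LCPO surface-area free energies on
    parametrised topologies and coordinate snapshots, computes
    sliding-window binding-energy profiles and their squared Pearson
    correlation with experimental affinities, and generates fully
    deterministic synthetic receptor-ligand panels so every pipeline
    stage is testable without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
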