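Package: hdxmd
Title: Differential HDX-MS and Molecular Dynamics Hydrogen-Bond Occupancy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for combined differential hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) and molecular dynamics (MD) analysis of protein-ligand
    binding. Detects backbone amide hydrogen bonds in MD trajectories with the
    Baker-Hubbard geometric criterion, computes per-replicate occupancies and
    significant free-vs-bound occupancy shifts, processes intact-protein and
    peptide-level deuteration data with in-exchange and back-exchange
    corrections, and links occupancy changes to measured HDX protection through
    simple semi-empirical per-residue metrics. Includes synthetic ground-truth
    generators (flickering two-state H-bond trajectories and deuterated isotope
    envelopes) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
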