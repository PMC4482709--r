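Package: poretraj
Title: Pore Hydration, Helix Dynamics and Chromophore Grafting Analysis for
    Molecular Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis of molecular dynamics trajectories of
    channel proteins, modelled on the workflows used to study early channel
    opening in channelrhodopsin. Reads and writes fixed-column (multi-model)
    PDB, performs Kabsch least-squares superposition with independent fit and
    measure selections, computes per-frame and per-residue RMSD, dynamic
    cross-correlation matrices of C-alpha displacements, residue-pair contact
    distance series with hysteresis-based hydrogen-bond/salt-bridge event
    detection, voxelised water-oxygen occupancy density maps (OpenDX output),
    membrane-spanning water-wire detection by graph connectivity, pore-radius
    profiles, and anchored rigid-fragment grafting for chromophore isomer
    replacement. Ships synthetic-data generators with planted ground truth
    (block-correlated helix bundles, water scenes with optional spanning
    wires, two-state contact series, toy retinal fragments) so every analysis
    is testable closed-loop without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
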