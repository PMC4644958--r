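Package: bindfe
Title: End-State Binding Free Energies and Bidirectional-Work Potentials of Mean Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for protein-inhibitor binding
    studies: single-trajectory MM-GBSA binding free energies (gas-phase
    Coulomb and Lennard-Jones interaction energies, Hawkins-Cramer-Truhlar
    generalized Born polar solvation, Shrake-Rupley surface-area nonpolar
    term) with per-residue decomposition and normal-mode entropy; structural
    analyses (Kabsch-superposed RMSD series, geometric hydrogen-bond
    detection and occupancy, distance series); and potential-of-mean-force
    estimation from segmented bidirectional steered-work samples via the
    Brownian-dynamics fluctuation-dissipation theorem, with Jarzynski and
    Bennett acceptance-ratio reference estimators. Ships seed-deterministic
    synthetic toy systems (host-guest complexes, jittered trajectories,
    Crooks-consistent work samples) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
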