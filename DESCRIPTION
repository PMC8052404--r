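Package: mdconf
Title: Conformational and Binding Free-Energy Analysis of Kinase MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics studies of kinase
    conformational preference and inhibitor binding. Reads reference
    structures and trajectories as (multi-model) PDB text, performs Kabsch
    superposition, iterative mean-structure computation, per-residue RMSF and
    per-frame RMSD; computes salt-bridge distance time series with window
    smoothing, occupancy and cleavage-event statistics, and active/inactive
    conformation classification; builds alpha-C helix orientational RMSD
    distributions against an inactive-state reference; and aggregates
    alchemical binding free energies from per-lambda-window work samples via
    the Bennett acceptance ratio, with Coulomb/van der Waals decomposition and
    replica-spread uncertainties. A synthetic-data module generates kinase-like
    scaffolds, Ornstein-Uhlenbeck/telegraph-process trajectories and
    Crooks-consistent work samples with closed-form ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
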