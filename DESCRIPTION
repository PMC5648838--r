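Package: dynophoreR
Title: Dynamic 3D Pharmacophore (Dynophore) Analysis of Protein-Ligand
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Perceives ligand pharmacophore features (hydrogen-bond donors
    and acceptors, positive and negative ionizable groups, hydrophobic
    contacts) and detects their geometric interactions with environment
    partners in every frame of a molecular dynamics trajectory. Per-frame
    interactions sharing the same feature type and ligand atoms are
    aggregated into superfeatures that are monitored spatially (aligned
    centroid point clouds), statistically (occurrence frequencies, partner
    frequencies, distance histograms) and sequentially (occurrence bar
    codes). Also provides the surrounding trajectory analyses: Kabsch
    rigid-body superposition on alpha carbons, RMSD and RMSF profiles, and
    sphere-bounded grid pocket volumes. A deterministic synthetic-system
    generator produces toy receptor-ligand trajectories whose per-frame
    interaction geometry follows a user-declared schedule, so every
    reported statistic has a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
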