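# dynophoreR

Dynamic 3D pharmacophore ("dynophore") analysis of protein–ligand
molecular-dynamics trajectories in R.

A static protein–ligand complex is classically summarized as a 3D
pharmacophore: the arrangement of hydrogen-bond donors (HBD) and
acceptors (HBA), positive and negative ionizable groups (PI/NI), and
hydrophobic contacts (H) the ligand presents to its target. A dynophore
extends this to a whole MD trajectory: a pharmacophore is perceived in
*every* frame, and all per-frame features that share the same
interaction type and the same ligand atoms are pooled into a
**superfeature** that is monitored three ways:

- **spatially** — each detected feature is reduced to the centroid of
  its ligand atoms in Cα-aligned coordinates, giving a 3D point cloud
  per superfeature;
- **statistically** — the *superfeature occurrence frequency* is
  100 × (frames with ≥ 1 detected interaction) / (all frames), and each
  environment partner's *interaction occurrence frequency* is
  100 × (frames where that partner interacts) / (superfeature
  occurrence frames), so simultaneous partners may sum above 100 %;
  distance distributions are reported as histograms;
- **sequentially** — boolean per-frame **bar codes** for each
  superfeature and each (superfeature, partner) pair.

The package also covers the trajectory analyses that surround a
dynophore study: Kabsch least-squares superposition on alpha carbons,
per-frame RMSD, per-atom/per-residue RMSF, and POVME-style
sphere-bounded grid pocket volumes (volume = grid spacing³ × free grid
points inside an inclusion sphere, hard-sphere occlusion by protein and
ion atoms). The motivating application is metalloenzyme–inhibitor
binding of the arginase kind — small amino-acid-like or boronate probes
anchored by a binuclear Mn²⁺/hydroxide cluster, with flexible loops
(serine/aspartate/arginine/threonine partners) gating the pocket — but
nothing in the package is specific to that system.

Because interaction-perception thresholds differ between tools, all
geometric criteria are explicit and configurable (defaults: H-bond
2.5–3.8 Å heavy-atom distance and D–H⋯A ≥ 130°, ionic ≤ 5.5 Å
centroid–centroid, hydrophobic ≤ 4.5 Å, metal coordination ≤ 3.0 Å).

A deterministic **synthetic-system generator** builds toy
receptor–ligand trajectories in which a user-declared schedule dictates
exactly which interaction is satisfied in which frame (with optional
bounded jitter and global rigid tumbling). Every statistic the package
reports therefore has a ground truth known by construction, which is
how the test suite and the acceptance script validate the pipeline
end to end.

## Worked example

Script a 500-frame toy complex — a hydroxyl donating to a backbone
carbonyl in frames 0–225, the carboxylate paired ionically with an
arginine-like guanidinium in frames 100–399, the aliphatic tail
touching a threonine-like methyl every 4th frame — under global rigid
tumbling, then analyze it:

```r
library(dynophoreR)

spec <- toySpec(
  n_frames = 500,
  ligand = "amino",
  schedules = list(
    schedule("HBD", "hydroxyl",    "bbO",    frames = 0:225),
    schedule("NI",  "carboxylate", "argGua", frames = 100:399),
    schedule("H",   "tail",        "thrMe",  frames = seq(0, 499, 4))),
  jitter_sigma = 0.1, seed = 42, rigid_tumble = TRUE)

toy <- generateToyTrajectory(spec)
dyn <- buildDynophore(toy$trajectory)   # align -> perceive -> detect -> pool
dyn
#> Dynophore: 3 superfeatures over 500 frames
#>   HBD[OG]          45.2%  partners: GLY/1/A
#>   NI[O1,O2]        60.0%  partners: ARG/5/A
#>   H[CB,CG,CD]      25.0%  partners: THR/6/A

sf <- superfeatures(dyn)[["HBD[OG]"]]
superfeatureFrequency(sf)   # 45.2  (226 of 500 frames)
partnerFrequency(sf)        # GLY/1/A: 100  (sole partner)
sum(distanceHistogram(sf)$counts)  # 226 events, one per occurrence frame
```

The scheduled fractions (226/500 = 45.2 %, 300/500 = 60.0 %,
125/500 = 25.0 %) are recovered exactly: the jitter is bounded inside
the criteria windows, and the Cα alignment removes the tumbling —
`pointCloud(sf)` collapses to a single point for rigid-only motion.
`exportReport(dyn, "out/")` writes the versioned JSON report,
per-partner summary CSV, bar-code CSV, and one pseudo-atom PDB cloud
per superfeature for viewing alongside the structure.

The same pipeline runs from the shell (`inst/scripts/dynophore`):

```sh
dynophore synth  --spec spec.json --out toy/
dynophore run    --topology toy/topology.pdb --trajectory toy/trajectory.pdb \
                 --out report/ [--criteria my.cfg] [--no-align] [--include-water]
dynophore metrics --topology top.pdb --trajectory traj.pdb --out metrics/
dynophore volume  --topology top.pdb --trajectory traj.pdb --out vol/ \
                  --center 1234 --radius 10
dynophore report  --in report/
```

Real systems are read from PDB topologies (explicit hydrogens; CONECT
bonds honored, otherwise inferred from covalent radii) with multi-model
PDB or DCD coordinates.

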