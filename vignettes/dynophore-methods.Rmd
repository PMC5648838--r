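---
title: "Dynophore analysis: models, parameters, and design choices"
author: "dynophoreR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynophore analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynophoreR)
```

## The model

A 3D pharmacophore abstracts a ligand–protein complex into typed
interaction features: hydrogen-bond donors (HBD) and acceptors (HBA),
positive and negative ionizable groups (PI/NI), and hydrophobic
contacts (H), conventionally drawn green, red, blue, orange and yellow.
A *dynophore* applies this abstraction to every frame of an MD
trajectory and pools the per-frame features: all features sharing the
same interaction type **and** the same ligand atoms form one
*superfeature*, a time-resolved entity with

* a **point cloud** — per occurrence frame, the unweighted centroid of
  the feature's ligand heavy atoms in Cα-aligned coordinates;
* **occurrence statistics** — the superfeature frequency is
  $100 \cdot |F_s| / N$ where $F_s$ is the set of frames with at least
  one detected interaction and $N$ the total frame count, and each
  environment partner's frequency is
  $100 \cdot |F_{s,p}| / |F_s|$, i.e. relative to the superfeature's
  own occurrences — simultaneous partners may therefore sum above
  100 %;
* **sequences** — boolean per-frame bar codes for the superfeature and
  for each partner, plus per-partner distance series binned into
  histograms.

Two modelling commitments deserve emphasis. First, a superfeature
*occurs* in a frame only when it has a detected environment interaction
there — mere existence of the chemical group does not count, since for
rule-based typing the group exists in every frame and all frequencies
would read 100 %. Reported frequencies are therefore interaction
times. Second, multiple geometric matches of the same (template,
partner, type) within one frame collapse to a single event carrying the
minimal qualifying distance, because a per-frame pharmacophore contains
a feature at most once.

### Feature perception rules

Typing is structural, over elements, bonds and formal charges:

* **HBD** — every O/N with at least one explicit hydrogen; one template
  per heavy atom, carrying all of its hydrogens.
* **HBA** — every O/N bearing a lone pair and not positively charged
  (quaternary/protonated N excluded, as are nitrogens inside positive
  groups). A tetrahedral borate is special-cased: it contributes a
  *single group acceptor* carried by the boron, and its hydroxyl
  oxygens act as donors only. Carboxylate oxygens, in contrast, keep
  one acceptor template per oxygen *in addition to* the grouped
  negative-ionizable template — per-oxygen H-bond statistics and a
  single charged feature coexist.
* **PI** — protonated amines (formal charge or four connections) and
  guanidinium/amidine carbon groups (C bonded to 3 N, the group is one
  template).
* **NI** — carboxylates (both oxygens in one template), tetrahedral
  borates/boronates (B plus its oxygens), sulfonates, phosphates,
  hydroxide-like charged O, and residual formally negative atoms.
* **H** — maximal connected components of carbons bonded only to
  C/H/S, kept when the component has ≥ 3 carbons. On the environment
  side any single C/S bonded only to C/H/S is a valid hydrophobic
  partner atom.

Every non-ligand residue is one environment partner, identified by
(residue name, number, chain) and classed protein / metal (Mn, Zn, Mg,
Ca, Fe, Na, K ions) / hydroxide / water / other-het. Water partners are
excluded from statistics by default (`include_water = FALSE`): bulk
water H-bonds would otherwise dominate every donor/acceptor
superfeature, and the interactions of interest are with the target and
its cofactors.

### Interaction criteria

Perception thresholds in commercial pharmacophore tools are not public,
so the detection windows here are ordinary literature geometric
criteria, fully exposed (`defaultCriteria()`, flat `key = value` config
files, `--criteria` on the CLI):

| parameter | default | meaning |
|---|---|---|
| `hbond_dist_min/max` | 2.5–3.8 Å | donor–acceptor heavy-atom distance |
| `hbond_angle_min` | 130° | D–H⋯A angle at the explicit hydrogen, best hydrogen wins |
| `ionic_dist_max` | 5.5 Å | charged-group centroid–centroid distance |
| `hydrophobic_dist_max` | 4.5 Å | closest apolar heavy-atom pair |
| `metal_coord_max` | 3.0 Å | NI–metal coordination, counted as the same ionic event class |

A charged group's position is its heavy-atom centroid (both carboxylate
oxygens, the four guanidinium atoms, boron plus its oxygens), matching
the centroid reduction used for the point clouds. When several
hydrogens could satisfy an H-bond, the geometrically best (largest)
angle decides and only one event is recorded. Donors lacking explicit
hydrogens are evaluated on heavy-atom distance alone, with a one-time
warning — results on topologies without hydrogens are correspondingly
softer. The hydrophobic criterion is a single closest-pair distance; no
buried-fraction requirement is imposed, which is a known divergence
risk against tools that demand more buried contact area.

Detection uses a cell-list neighbor search (cell edge = the relevant
cutoff) for the atom-pair feature types and plain centroid distances
for the ionic types; `method = "brute"` forces the all-pairs scan. The
two paths return identical event multisets — a tested invariant, since
the cell list only prunes candidates and every surviving pair is
re-checked exactly.

## Alignment and trajectory metrics

Frames are superposed on the Cα atoms (any selection expression may be
substituted) onto frame 0 by the Kabsch algorithm: SVD of the
cross-covariance matrix with a determinant correction restricting the
solution to proper rotations. Frame 0 is the reference by default
purely for determinism; any frame index can be chosen. Degenerate fits
(< 3 atoms, collinear sets, singular value below 1e-9) raise errors
rather than returning reflections or noise-amplified rotations.

RMSD is measured per frame over a selection after an optional Cα
pre-fit; RMSF per atom about its time-average position on the aligned
trajectory, with an optional per-residue mean. Both have closed-form
and brute-force oracle tests.

Pocket volume follows the hard-sphere grid scheme: an inclusion sphere
(default radius 10 Å, e.g. around an inhibitor's boron atom) is
sampled on a cubic grid (default spacing 0.5 Å, required ≤ radius/5),
and points inside any occluder's van der Waals + probe sphere are
removed; volume = spacing³ × free points. Protein and ion atoms
occlude; the ligand and water are excluded from the occluders by
default, since the question is how much cavity the binding site offers.
Probe radius defaults to 0 and there is no contiguity filtering of free
grid points — the simplest defensible scheme, declared rather than
inferred, and configurable. The grid converges as spacing shrinks
(tested against a 0.1 Å oracle) and the empty 10 Å sphere reproduces
4πr³/3 within 2 % at 0.5 Å spacing.

## The synthetic system

`toySpec()` / `generateToyTrajectory()` build a toy receptor–ligand
complex whose geometry is scripted frame by frame, so that every
statistic has a known ground truth without any external input. The
receptor is a ring (radius 10 Å) of pseudo-residues, each presenting
one site on an inward approach axis: two backbone carbonyl acceptors
(`bbO`, `bbO2`, 3.4 Å apart), a serine-like donor/acceptor hydroxyl
(`serOG`), an aspartate-like carboxylate (`aspCOO`), an arginine-like
guanidinium (`argGua`, plane perpendicular to the approach axis so its
N–H donors cannot accidentally hydrogen-bond a scheduled ionic guest),
a threonine-like methyl (`thrMe`), two Mn²⁺ ions 2.8 Å apart and a
hydroxide — the partner inventory of a binuclear metalloenzyme site.
Cα anchor atoms at radius 13 Å carry the alignment. The ligand probe is
either amino-acid-like (carboxylate, protonated amine, hydroxyl,
3-carbon tail) or a boronate (tetrahedral B(OH)₃⁻ plus an ethyl tail
too short to type as hydrophobic).

A schedule `(type, ligand group, partner, active frames, on, off)`
moves the group's atoms along the partner's approach axis to the `on`
distance in active frames and to the `off` distance otherwise; donor
hydrogens point at the acceptor when active and away when not. Two
simultaneously active schedules on one group are solved by sphere–sphere
intersection (choosing the solution nearest the origin; for a shared
donor the hydrogen direction maximizes the smaller of the two D–H⋯A
angles by grid search). Three or more, or unreachable partner pairs,
raise a feasibility error naming the frame — e.g. one hydroxyl cannot
donate to both backbone acceptors at 2.9 Å each, because no hydrogen
direction achieves 130° to both (the attainable maximum is ≈ 128°).

Jitter is Gaussian on the scheduled distances, seeded, truncated at 3σ
*and clipped at 95 % of the validated window margin*; `toySpec()`
additionally requires 3σ ≤ margin. Truncation at 3σ alone would not
guarantee that jittered distances stay on their side of the criteria
windows, so the clip is what makes schedule-exactness a theorem rather
than a high-probability event. Optional rigid tumbling applies a
uniform random rotation (quaternion) plus a translation to the whole
frame; Cα alignment removes it exactly, which the tests verify via
point-cloud collapse (< 1e-6 Å spread) and zero fitted RMSD.

After placing every group, the generator brute-verifies each frame: all
(ligand feature, partner) pairs are checked directly against the
criteria, and generation aborts unless exactly the scheduled pairs
fire. The emitted ground truth is then pure schedule arithmetic.
Determinism is bitwise: the same spec yields byte-identical PDB and
JSON outputs, and the generator restores the caller's RNG state.

What the toy does **not** emulate: force-field energetics, solvent,
thermal ensembles, correlated loop motions, realistic covalent geometry
under group movement (bonds may stretch — detection depends only on
interatomic geometry, and bonds travel in CONECT records), or the
atomic detail of real arginase complexes. Passing tests demonstrate the
*bookkeeping and geometry* of the pipeline are exact, not that the
default criteria reproduce any particular tool's perception on real
trajectories.

## Numerical and interface choices

* Coordinates are Å, times ps, residue numbers verbatim from the input
  (1-based, crystal numbering), frame indices 0-based everywhere.
* Bond inference (used only without CONECT records): distance below
  1.6 × the covalent-radius sum, never involving metals; CONECT always
  wins. Elements missing from the element column derive from atom-name
  first letters per PDB v3 conventions.
* Histograms span from the minimal observed distance rounded down to
  0.1 Å up to the feature type's distance cutoff, bin width 0.1 Å,
  half-open `[lo, hi)` bins with the last bin closed, so counts always
  sum to the event count.
* Frequencies are exported at one decimal in CSVs (the conventional
  reporting precision) and at full precision in the JSON report, which
  is the round-trip format.
* Exported point clouds are pseudo-atom PDBs (residue name = feature
  type, B-factor = frame index mod 1000) readable by standard viewers.
* I/O: PDB (multi-model) and DCD are supported, via bio3d underneath;
  XTC is not (no installed R reader), and PSF/TPR topology building,
  periodic-box unwrapping and protonation assignment are out of scope —
  inputs are taken as prepared, whole, and protonated.
* CLI exit codes: 0 success, 1 domain error, 2 usage error; logs to
  stderr, data to files; every output directory contains a
  `provenance.json` with the package version, schema version and the
  exact options used.

## Problem sizes

The test suite and the acceptance script run on synthetic systems of
~40–45 atoms with 10–1000 frames, 22–25 random frames for the
detection-equivalence checks, 6-point sets for the rotation-grid
oracle, and 10 Å/0.5 Å volume grids (~33,000 sphere points, up to
~3,500 occluders) — sizes chosen so the whole suite completes in about
a minute while still exercising every code path at full precision.

## Known limitations

Aromatic/π-stacking and halogen-bond features are not modelled. The
hydrophobic single-distance criterion and the merged NI/metal
coordination class are declared approximations. Rule-based typing
trusts the input's explicit hydrogens and formal charges; no
protonation or tautomer reasoning is attempted. Conformational
clustering of trajectories is out of scope.
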