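---
title: "Direct interaction fingerprints from protein–ligand structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct interaction fingerprints from protein–ligand structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifpr)
```

## The method

A structural interaction fingerprint encodes, for every residue of a
binding site, which interaction types that residue forms with a bound
ligand. `ifpr` computes these fingerprints *directly* from complex
structure files — a single PDB, MOL2 or PDBQT structure, or a multi-MODEL
PDB holding a series of molecular-dynamics snapshots — with no dependency
on docking output. Each residue receives a fixed-order 7-bit vector:

| bit | name             | meaning (protein perspective)              |
|----:|------------------|--------------------------------------------|
| 1   | `hydrophobic`    | apolar–apolar contact                       |
| 2   | `aromatic_f2f`   | face-to-face ring stacking                  |
| 3   | `aromatic_e2f`   | edge-to-face (T-shaped) ring stacking       |
| 4   | `hbond_donor`    | residue donates a hydrogen bond             |
| 5   | `hbond_acceptor` | residue accepts a hydrogen bond             |
| 6   | `ionic_cation`   | residue cation ↔ ligand anion salt bridge   |
| 7   | `ionic_anion`    | residue anion ↔ ligand cation salt bridge   |

Labels in the output tables use the same perspective, so `H-bond (Donor)`
always means the *protein* donates. When a structure's own prose describes
the ligand as "the acceptor" of a bond, that is the same physical contact
as a protein-donor row here; we standardize on the protein view because
occupancy tables are residue-indexed.

Over an ordered snapshot series the per-frame bits are aggregated into
**interaction hotspots**: for each (residue, type) pair, the occupancy

$$\mathrm{occupancy} = 100 \times \frac{\#\{\text{frames with bit set}\}}{n_\text{frames}}$$

expressed in percent. Residues whose occupancy exceeds a threshold
(default 10%) are reported as the dominant interaction partners of the
simulation.

## Geometric detectors and their parameters

The detectors follow the classical seven-type structural-IFP convention.
The thresholds are deliberately conventional defaults — different
fingerprinting tools use slightly different numbers, so every value can be
overridden through `ifp_config()`:

| parameter          | default | units | role                                   |
|--------------------|--------:|-------|----------------------------------------|
| `hydrophobic_dist` | 4.5     | Å     | max apolar–apolar atom distance         |
| `hbond_dist`       | 3.5     | Å     | max donor–acceptor heavy-atom distance  |
| `hbond_angle`      | 135     | °     | min D–H…A angle (explicit H only)       |
| `ionic_dist`       | 4.0     | Å     | max cation-group ↔ anion-group distance |
| `f2f_dist`         | 4.5     | Å     | max ring-centroid distance, stacked     |
| `f2f_angle`        | 30      | °     | max interplanar angle, stacked          |
| `e2f_dist`         | 5.5     | Å     | max centroid distance, T-shaped         |
| `e2f_angle`        | 60      | °     | min interplanar angle, T-shaped         |
| `metal_dist`       | 2.8     | Å     | max metal ↔ ligand N/O/S distance       |
| `site_cutoff`      | 6.0     | Å     | automatic binding-site selection radius |

All comparisons are inclusive (`<=`, `>=`), so a pair placed exactly at a
cutoff counts as interacting. Interplanar angles are folded to the acute
range; with the default windows the face-to-face and edge-to-face bits are
mutually exclusive for any single ring pair (30° < θ < 60° sets neither).

Ring planes are least-squares fits (SVD of the centered ring coordinates);
the plane fit is coordinate-frame independent, which makes every detector
invariant under rigid motion of the whole complex — a property the test
suite verifies over randomly drawn rotations and translations.

**Hydrogen-free structures.** MD exporters differ in whether snapshot PDBs
keep hydrogens. When a donor has explicit hydrogens the D–H…A angle
criterion applies (best hydrogen wins); when it has none, the distance
criterion alone decides. Both paths are exercised in the tests; the angle
gate simply vanishes with the hydrogens, which can only make detection more
permissive.

**Metals.** Monoatomic ions (Zn²⁺, Ca²⁺, Mg²⁺, …) are recognized by
residue name — a PDB file carries no charge column. Ligand N/O/S atoms
within `metal_dist` of an ion are reported per frame, but *alongside* the
7-bit residue vectors rather than inside them: hotspot tables are
residue-indexed and a metal ion is not a residue. The metal contacts get
their own occupancy table (`aggregate_metal_contacts()`), which matters for
zinc metalloproteinases where a carboxylate ligand coordinates the
catalytic Zn²⁺ throughout a trajectory.

## Role perception

Protein residues are annotated from a shipped template
(`inst/extdata/residue_roles.tsv`; see `residue_templates()`): apolar atoms
are side-chain carbons/sulfurs with no bonded N/O, cation groups are the
lysine ammonium and arginine guanidinium, anion groups the aspartate and
glutamate carboxylates, rings the PHE/TYR/HIS systems and both tryptophan
rings; every backbone N donates and every backbone O accepts. A residue
carrying OXT contributes a terminal carboxylate. Nonstandard residues are
skipped with a warning rather than an error — the fingerprint is then
honestly incomplete, and the template file format lets users extend
coverage.

**Histidine** is neutral by default (NE2 donor, ND1 acceptor — the common
tautomer), because protonation is genuinely ambiguous at pH 7.4 and
His residues frequently coordinate catalytic metals, where a protonated
imidazole would be wrong. `ifp_config(his_charged = TRUE)` switches every
histidine to the doubly protonated cation.

Ligands are perceived from their topology: bonds come verbatim from MOL2
blocks or, for PDB/PDBQT input, from a covalent-radius rule
(`dist <= r_i + r_j + 0.45 Å`, and `> 0.4 Å` to reject duplicate atoms).
Ionization is rule-based at pH 7.4 rather than pKa-calculated: carboxylic
acids are deprotonated into an anion group spread over both oxygens,
aliphatic amines protonated into cations, phenols/alcohols are
donor + acceptor, carbonyl and ether oxygens acceptors. A caffeate-like
phenylpropanoid therefore carries one anion group (the carboxylate), two
phenolic donor/acceptor oxygens and one aromatic ring. Rule-based
ionization mirrors how structures are typically prepared ("set pH to 7.4")
and keeps the assignment deterministic; tautomer enumeration and
resonance-aware charges are out of scope. Cysteine sulfur is treated as
apolar, the common fingerprinting practice.

A ring is aromatic iff it has 5 or 6 members, all C/N/O/S, no ring carbon
with more than 3 heavy neighbours, and is planar within 0.10 Å of its
least-squares plane. A chair cyclohexane (puckering ≈ 0.25 Å) fails the
planarity test; SYBYL `.ar` types from MOL2 input override geometry.

## RMSD machinery

Three related quantities support binding-stability analysis:

- `rmsd_backbone()` — Kabsch-superposes the frame's backbone (N, CA, C, O)
  onto the reference and reports the RMSD over that selection. "Backbone"
  is taken as those four atoms per residue; tools differ on including O,
  and the choice is documented rather than configurable.
- `rmsd_ligmove()` — superposes on the *backbone only*, then measures the
  ligand heavy-atom RMSD **without further fitting**, so genuine ligand
  displacement relative to the receptor frame is what remains. The
  companion rule flags a pose *stable* when the value is below 2.000 Å.
  Whether the receptor fit should use backbone or all heavy atoms is not
  standardized across MD packages; backbone is chosen here (and stated)
  because it is insensitive to side-chain motion.
- `rmsd_pose()` — plain heavy-atom RMSD between two poses in identical
  atom order, no superposition: the redocking validation metric, accepted
  at ≤ 2.000 Å. No symmetry correction is applied (a 180° carboxylate
  flip counts as displacement); this is a documented limitation.

The reference frame for both traces is frame 0 — the docked starting
pose — and the time axis assumes a fixed snapshot interval (default
100 ps). Kabsch superposition uses the SVD construction with the
determinant correction, so the returned rotation is always proper; the
test suite checks optimality against a numeric minimizer over rotations
and against an independent structural-bioinformatics implementation.

## The synthetic-complex generator

Real trajectories from the motivating use case are not publicly deposited,
so correctness is established on synthetic complexes whose geometry is
*exactly* known. `make_complex_fixture()` emits one idealized residue
(hard-coded internal coordinates, so tests need no external library), one
ligand motif (benzene, acetate, methylammonium, methanol, methane, or a
caffeate-like phenylpropanoid), and optionally a metal ion, placed so that
the requested anchor distance, ring angle, and D–H…A angle hold
analytically; the realized geometry is re-measured from the emitted
coordinates and echoed in a sidecar table. `make_trajectory_fixture()`
turns a base complex into a multi-MODEL series where a *bound schedule*
dictates exactly which frames carry the interaction — the schedule is the
oracle for every occupancy assertion. Unbound frames translate the ligand
50 Å along +x, far beyond every cutoff; optional Gaussian jitter (ligand
atoms only, fixed seed) perturbs coordinates without touching the protein,
so role perception stays constant and the schedule remains exact for small
σ.

What the generator deliberately does **not** emulate: force-field physics,
solvent, thermal backbone fluctuation, conformational change, partial or
intermittent interactions at threshold boundaries. Passing tests therefore
demonstrate that the geometric bookkeeping is exact — they do not
demonstrate that the default thresholds are the "right" chemistry for any
particular system, which is precisely why every threshold is exposed.

## Numerical choices

- **Occupancy rounding** is half-up at the second decimal
  (`floor(100 x + 0.5) / 100`). Published hotspot tables are not always
  consistent between rounding and truncation, so one convention is fixed
  and stated: a 501-frame series with 238 set frames is 47.5049…%, printed
  as 47.50%.
- **Zero-occupancy rows are omitted**, matching the convention of listing
  only observed interactions. An empty table is therefore meaningful
  ("nothing interacted"), and `aggregate_hotspots()` refuses only an empty
  *series*.
- **Ties at cutoffs are inclusive** everywhere, matching the stated
  inequalities.
- **Alternate locations**: only blank or `'A'` conformers are kept, giving
  a deterministic single conformer.
- **Parsing**: fixed-column PDB first, whitespace-split fallback per line
  (MD exporters produce loose PDB); a line that fails both raises a parse
  error naming the line number. Multi-MODEL series must carry an identical
  atom sequence in every frame; the check is structural, not coordinates.
- **IC50** uses base-10 logarithms and unweighted ordinary least squares
  of percent inhibition on log concentration, inverted at the 50%
  crossing: IC50 = 10^((50 − b)/m). A sigmoidal (4-parameter logistic) fit
  is intentionally not provided — the supported workflow is the linear
  regression on the log scale, and pretending otherwise would change the
  estimator. Whether replicate wells are averaged before or after the
  regression is left to the caller (both enter as rows).
- **Problem sizes** used by the checks: detector sweeps run ~33 complexes
  spanning all seven types at cutoff ± 0.1 Å; invariance uses 100 random
  rigid motions; Kabsch optimality uses 1000 random point-set pairs;
  schedule recovery uses a 501-frame series. These sizes make the full
  suite run in well under a minute per file while still exercising each
  property densely.

## Worked example

```{r example, eval = FALSE}
library(ifpr)

# a salt-bridge complex: lysine ammonium 3.0 A from a carboxylate oxygen
fx <- make_complex_fixture(complex_spec("LYS", "acetate", distance = 3.0))
fx$measured

# an 8-frame trajectory bound in frames 0-2
traj <- make_trajectory_fixture(trajectory_spec(
  complex_spec("LYS", "acetate", distance = 3.0),
  n_frames = 8, bound_schedule = 0:2))

series <- read_pdb(traj$text)
fps <- direct_ifp_series(series, ligand = "LIG")
aggregate_hotspots(fps)      # 37.50% for H-bond (Donor) and Ionic (Cation)
rmsd_traces(series, "LIG")   # ligand parked 50 A away in frames 3-7
```

## Known limitations

- Water-mediated bridges, halogen bonds and cation–π are not distinct
  types; they either fold into the seven types or go undetected.
- No pKa calculation: unusual ionization states need a pre-protonated
  input or an extended template.
- `rmsd_pose()` has no graph-automorphism symmetry correction.
- mmCIF and binary trajectory formats (DCD/XTC) are not read; snapshot
  series are expected as multi-MODEL PDB.
- Per-atom interaction energies are out of scope: bits are geometric.
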