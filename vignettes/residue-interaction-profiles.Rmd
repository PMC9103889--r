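---
title: "Methods: probe occupancy maps and residue interaction profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe occupancy maps and residue interaction profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`probemap` analyses mixed-solvent MD trajectories of one protein plus many
copies of a small probe.  The statistical object is the voxelised occupancy
of probe heavy atoms near the protein surface, and, downstream of it, the
distribution of residue positions around surface-bound probe poses
expressed in the probe's own reference frame.

The chain is: per-run **PMAP** (occupancy of probe heavy atoms on a 1 Å
lattice, restricted to the 5 Å shell `V` around protein heavy atoms and
scaled to unit sum over `V`), the per-voxel **max-PMAP** across independent
runs, the **preferable surface** `{v : max-PMAP(v) >= theta}`, per-pose
**residue environments** (all residues with a heavy atom within 4 Å of any
probe heavy atom), a symmetry-aware Kabsch superposition of each
environment onto the reference probe, and per-residue-type **Cβ count
grids** — the residue interaction profile.  An optional **stability
filter** drops poses that moved 3 Å or more (strictly: keeps `< 3 Å`) over
the preceding 500 ps.

Assumptions inherited from the experimental design:

* trajectories are pre-imaged (probes wrapped to the protein-centred
  image) and boxes are orthorhombic;
* "heavy atom" means element ≠ H/D everywhere — hydrogens are parsed and
  kept but excluded from every distance and binning computation;
* the probe is rigid enough that a fixed set of designated alignment atoms
  defines its frame; symmetry-equivalent atom labelings are supplied
  explicitly per probe (presets ship for benzene, catechol, benzamidine —
  aligned on all carbons for benzamidine, all heavy atoms otherwise).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| grid spacing | 1.0 | Å | voxel edge; occupancy and profile lattice |
| grid margin | 8.0 | Å | extent beyond the protein bounding box |
| shell cutoff | 5.0 | Å | defines `V` from protein heavy atoms |
| surface theta | 0.2 | – | inclusive max-PMAP threshold |
| environment cutoff | 4.0 | Å | inclusive heavy-atom contact rule |
| stability lag | 500 | ps | displacement look-back window |
| stability cutoff | 3.0 | Å | strict upper bound for "stable" |
| schedule | 20–40 ns, 10 ps | – | `(t_start, t_end]` sampling times |
| runs | 20 | – | independent repeats combined by max |
| profile half-extent | 8 | Å | probe-centred profile cube |

Every default is the protocol value the analysis was designed around; the
YAML config (`load_validate_config()`) overrides any of them and rejects
unknown keys.  The snapshot schedule uses the half-open `(t_start, t_end]`
convention, the one under which a 20–40 ns window at 10 ps yields exactly
2000 snapshots.

## Frames and geometry

**Voxel ownership** is half-open with floor indexing: voxel `(i,j,k)`
covers `[origin + (idx-1)*spacing, origin + idx*spacing)`, so a point on a
shared face belongs to the higher-index voxel — deterministic and
testable.  **Shell membership** is measured from voxel centers, the common
convention for density masks.  `grid_from_points()` snaps the origin down
to the spacing lattice so voxel boundaries are reproducible against
sub-voxel shifts of the bounding box.

**Common frame across runs.**  Independent runs must share one grid before
a voxelwise max is meaningful.  Each run is rigidly fitted (Kabsch on
protein Cα atoms, proper rotations only) onto a shared reference snapshot,
by default the first run's first frame.  With `canonical_frame: true` the
reference is first rotated into the deterministic principal-axes frame of
its Cα atoms (centroid at origin, covariance eigenvectors as axes, signs
fixed by the third central moment, handedness enforced).  In that mode the
whole pipeline output is invariant under any global rigid transform of the
inputs — the invariance the test suite asserts exactly, voxel counts
included.  The default keeps the user's frame, which preserves any
deliberate alignment of the input with the lattice.

**Shell from the reference snapshot.**  `V` is built once from the
reference snapshot's protein heavy atoms, not per-frame unions, so that a
single constant mask serves all runs and the max-PMAP is well defined.
For the rigid or near-rigid proteins this analysis targets the difference
is immaterial; strongly flexible proteins would blur the shell either way.

**Occupancy counting** is per heavy atom per frame (a probe contributes as
many counts as it has heavy atoms in the shell), the literal reading of
voxel occupancy of probe heavy atoms.

## Superposition and symmetry

Environments are mapped into the reference probe frame by least-squares
rigid superposition of the designated alignment atoms, computed once per
symmetry-equivalent atom mapping; the minimal-RMSD mapping wins.
Reflections are never returned: if the best orthogonal fit is improper,
the best proper rotation is used and the larger RMSD reported honestly.

Two numerical points deserve record:

* **Planar degeneracy.**  For a planar alignment set — in particular any
  3-atom set — a mirror-related mapping reaches *exactly* the same optimal
  RMSD, because reflecting a planar configuration through its plane is a
  proper rotation.  A strict `<` comparison would then select the winner
  by ~1e−16 floating-point noise, which breaks bit-reproducibility and the
  rigid-transform invariance of profiles.  The selection therefore uses a
  1e−6 Å tolerance and prefers the earliest-listed mapping on ties.
* **Ring relabelings are rotations.**  A benzene ring rotated 60° in-plane
  fits its reference at RMSD ≈ 0 even *without* symmetry mappings, since
  the label shift is itself a proper rotation of the planar ring.
  Mappings become essential only when a relabeling would require a
  reflection (non-planar equivalent atoms) — the shipped tests construct
  exactly that case — and for keeping the *reported* RMSD meaningful when
  jitter breaks planarity.

Degenerate inputs (collinear or coincident alignment atoms) raise an
underdetermined-fit error; during environment extraction such poses are
skipped and counted rather than aborting the batch.

## What the synthetic generator emulates

The generator plants geometry, not physics: no forces, no thermostats,
only the occupancy statistics the analysis consumes.

* A compact rigid pseudo-fold on a 3.8 Å snake lattice, residues with
  N/CA/C/O/Cβ at standard bond lengths (no Cβ for glycine), composition
  roughly natural.
* Each hotspot has a designated probe copy that sits on it with the stated
  occupancy probability per frame — anchored by the probe's first
  alignment atom at the hotspot center, with isotropic Gaussian jitter
  (σ = 0.3 Å) and a random symmetry relabeling — and is otherwise placed,
  like all remaining copies, uniformly in the box at ≥ 6 Å from protein
  heavy atoms (outside the 5 Å shell), in a random orientation.
* A residue of the declared type is planted with its Cβ at a declared
  offset from the hotspot; the default offset puts the Cβ 3 Å from the
  probe centroid along the probe's symmetry axis, a tight but realistic
  heavy-atom contact.  Because the offset lies on the symmetry axis, its
  reference-frame image is immune to which symmetry mapping wins.

**Why a 3-heavy-atom default probe.**  PMAP mass at the hotspot voxel is
roughly `P(|N(0, 0.3)| < 0.5)^3 / n_atoms ≈ 0.74 / n_atoms` of the shell
total when bulk copies are excluded from the shell.  With 3 heavy atoms
that is ≈ 0.25, above the 0.2 surface threshold; a 6-atom benzene-sized
template would cap at ≈ 0.12 and could never clear the documented
threshold at the stated occupancy of 0.5.  The template is therefore a
small C2v carboxylate-like fragment (one carbon, two symmetry-equivalent
oxygens), which also exercises the symmetry-mapping code path by default.
The hotspot is placed on a half-integer lattice point so it coincides with
a voxel center of the snapped analysis grid — the configuration in which
the occupancy calculus above holds; this is the documented reference
configuration, chosen analytically, not tuned.

What a green test does **not** establish: realistic energetics, water
competition, probe–probe interactions, protein flexibility, or the actual
magnitude of published filter-removal fractions — all of those require
real MD.  The generator validates the *bookkeeping and geometry* of the
analysis: normalization, masking, gating, superposition, binning,
filtering, and their statistical behaviour under known occupancy.

## Other design choices

* **On-surface detection**: ≥ 1 probe heavy atom inside a member voxel
  (the most permissive reading), configurable to `centroid` or `all`.
* **Boundaries**: `>= theta` and `<= 4 Å` inclusive; `< 3 Å` strict, so a
  displacement of exactly 3.0 Å is unstable.
* **Stability anchor**: the probe heavy-atom centroid (configurable to a
  named atom); displacements use the minimum image so a periodic wrap is
  not a jump.  Environments in the first lag window, which have no
  verdict, are dropped and reported separately; the removed fraction is
  computed over environments that had a verdict.
* **Profile extent**: a ±8 Å cube around the reference probe centroid;
  residues whose selected atom falls outside are counted but not binned.
  Any atom name can be profiled (`atom_selector`), defaulting to Cβ
  because side-chain tips reorient too easily to characterise the residue
  environment.
* **His is basic** regardless of the protonation state in the input, per
  the fixed typing scheme; the scheme is a data file users can replace.
* **Empty preferable surface** warns instead of failing so threshold
  sweeps stay scriptable; degenerate normalization (no probe mass in the
  shell) is an error because every downstream quantity is undefined.
* **Tolerances**: normalization is checked to 1e−9 relative; OpenDX text
  round-trips to 1e−6 absolute (values are written with 9 significant
  digits, and geometry additionally lands in a JSON sidecar at full
  precision).

## Limitations

Orthorhombic boxes only; multi-model PDB is the only trajectory format
(convert XTC/DCD externally); no Gaussian smoothing, grand-canonical
reweighting, or free-energy conversion of occupancies; no automatic
perception of probe symmetry — mappings are explicit, auditable inputs.
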