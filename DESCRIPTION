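Package: probemap
Title: Probe Occupancy Maps and Residue Interaction Profiles from
    Mixed-Solvent Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("probemap", "authors", role = c("aut", "cre"),
    email = "probemap@example.org")
Description: Analysis of cosolvent (mixed-solvent) molecular dynamics
    trajectories of a protein co-solvated with copies of a small probe
    molecule.  Computes voxel occupancy probability maps (PMAP) of probe
    heavy atoms restricted to the protein surface shell, combines
    independent runs into a per-voxel maximum map (max-PMAP), thresholds
    it into a preferable protein surface, extracts the residue
    environment around every surface-bound probe pose, superposes the
    environments onto a reference probe frame (symmetry-aware Kabsch
    fit), and aggregates per-residue-type C-beta count grids into a
    probe-centred residue interaction profile.  Includes a stability
    filter for transient poses, OpenDX grid export, a multi-model PDB
    trajectory reader/writer, a synthetic trajectory generator with
    planted hotspots for validation, and a command line interface.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
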