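# Synthetic trajectory generator.  It plants geometry, not physics: a
# compact rigid pseudo-fold, probe copies that either sit on a planted
# hotspot (with a known occupancy probability, thermal-like jitter and a
# random symmetry rotation) or drift in the bulk away from the protein, and
# planted residues whose C-beta sits at a known offset from the hotspot.
# Every downstream statistic of the analysis is thereby known by
# construction.

AMINO3 <- list(
  acidic = c("ASP", "GLU"),
  basic = c("ARG", "HIS", "LYS"),
  hydrophilic = c("ASN", "CYS", "GLN", "SER", "THR"),
  hydrophobic = c("ALA", "ILE", "LEU", "MET", "PRO", "VAL"),
  aromatic = c("PHE", "TRP", "TYR"),
  glycine = "GLY"
)

# random proper rotation matrix (uniform via normalized quaternion)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# backbone + C-beta atoms of one residue, given the CA position and an
# orthonormal local frame (u, p, q); bond lengths are the standard values,
# angles merely plausible -- the analysis only ever uses distances and the
# C-beta position
residue_atoms_local <- function(resname, ca, u, p, q) {
  names <- c("N", "CA", "C", "O")
  coords <- rbind(
    N = ca + 1.46 * (0.33 * u + 0.944 * p),
    CA = ca,
    C = ca + 1.52 * (0.33 * u - 0.944 * p),
    O = ca + 1.52 * (0.33 * u - 0.944 * p) + 1.23 * q
  )
  elements <- c("N", "C", "C", "O")
  if (toupper(resname) != "GLY") {
    names <- c(names, "CB")
    coords <- rbind(coords, CB = ca + 1.53 * u)
    elements <- c(elements, "C")
  }
  list(names = names, coords = coords, elements = elements)
}

#' Generate a compact toy protein
#'
#' Residues are laid out on a snake-ordered cubic lattice with 3.8 Angstrom
#' neighbour spacing (a compact pseudo-fold) with randomized side-chain
#' orientations; each residue carries N, CA, C, O and (except glycine) a CB
#' atom at 1.53 Angstrom from CA.  Deterministic under `seed`.
#'
#' @param n_residues Number of residues (>= 3).
#' @param composition Named non-negative weights over
#'   `acidic`, `basic`, `hydrophilic`, `hydrophobic`, `aromatic`,
#'   `glycine`; defaults approximate natural abundance.
#' @param seed Optional RNG seed.
#' @return An atom table (see [atom_table()]) of protein atoms, chain `"A"`.
#' @export
generate_toy_protein <- function(n_residues = 30,
                                 composition = c(acidic = 0.12, basic = 0.12,
                                                 hydrophilic = 0.22,
                                                 hydrophobic = 0.32,
                                                 aromatic = 0.12,
                                                 glycine = 0.10),
                                 seed = NULL) {
  if (!is.numeric(n_residues) || n_residues < 3)
    stop_config("'n_residues' must be >= 3")
  bad <- setdiff(names(composition), names(AMINO3))
  if (length(bad) || is.null(names(composition)) ||
      any(composition < 0) || sum(composition) <= 0)
    stop_config("'composition' must be non-negative named weights over: %s",
                paste(names(AMINO3), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n_residues <- as.integer(n_residues)

  # snake-ordered lattice keeps consecutive CA 3.8 A apart and the fold compact
  side <- ceiling(n_residues^(1 / 3))
  idx <- 0L
  ca <- matrix(NA_real_, n_residues, 3L)
  for (kz in seq_len(side)) for (ky in seq_len(side)) for (kx in seq_len(side)) {
    if (idx >= n_residues) break
    idx <- idx + 1L
    gx <- if (ky %% 2L == 1L) kx else side + 1L - kx
    gy <- if (kz %% 2L == 1L) ky else side + 1L - ky
    ca[idx, ] <- 3.8 * c(gx, gy, kz)
  }

  types <- sample(names(composition), n_residues, replace = TRUE,
                  prob = composition / sum(composition))
  resnames <- vapply(types, function(ty) {
    pool <- AMINO3[[ty]]
    if (length(pool) == 1L) pool else sample(pool, 1L)
  }, character(1))

  rows <- vector("list", n_residues)
  for (r in seq_len(n_residues)) {
    R <- random_rotation()
    ra <- residue_atoms_local(resnames[r], ca[r, ], R[, 1], R[, 2], R[, 3])
    rows[[r]] <- atom_table(name = ra$names, resname = resnames[r],
                            chain = "A", resno = r, coords = ra$coords,
                            element = ra$elements)
  }
  do.call(rbind, rows)
}

#' Random probe placement with a separation constraint
#'
#' PACKMOL-like rejection sampling of probe center positions uniform in an
#' orthorhombic box, with all pairwise minimum-image distances at least
#' `min_separation` (mimicking the anti-aggregation restraint between probe
#' centers).
#'
#' @param box Box lengths in Angstrom (3-vector).
#' @param n_probes Number of positions.
#' @param min_separation Minimum pairwise (minimum-image) distance in
#'   Angstrom.
#' @param seed Optional RNG seed.
#' @param max_attempts Attempt budget per probe (default 2000).
#' @return An `n_probes x 3` matrix of positions.
#' @export
random_probe_placement <- function(box, n_probes, min_separation, seed = NULL,
                                   max_attempts = 2000) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop_config("'box' must be 3 positive lengths")
  if (!is.numeric(n_probes) || n_probes < 1) stop_config("'n_probes' must be >= 1")
  check_scalar_number(min_separation, "min_separation", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(NA_real_, n_probes, 3L)
  for (i in seq_len(n_probes)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- stats::runif(3) * box
      if (i == 1L) { ok <- TRUE } else {
        delta <- sweep(pos[seq_len(i - 1L), , drop = FALSE], 2L, cand, "-")
        delta <- min_image_delta(delta, box)
        ok <- all(rowSums(delta^2) >= min_separation^2)
      }
      if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop_data("packing infeasible: could not place probe %d of %d at separation %g in a %s box",
                i, n_probes, min_separation, paste(box, collapse = " x "))
  }
  pos
}

#' Describe a planted hotspot ground truth
#'
#' @param hotspots `n x 3` matrix (or 3-vector) of hotspot centers in
#'   Angstrom.
#' @param occupancy Per-hotspot probability, in `(0, 1]`, that the hotspot's
#'   designated probe copy sits on it in a given frame.
#' @param residues List (one per hotspot) of
#'   `list(resname =, offset =)`: the residue planted next to the hotspot
#'   and the offset of its C-beta from the hotspot center.  `offset = NULL`
#'   lets the generator pick its documented default (3 Angstrom from the
#'   probe centroid along the probe's symmetry axis).
#' @param box Box lengths in Angstrom.
#' @param seed Seed recorded with the truth.
#' @return An object of class `planted_truth`.
#' @export
planted_truth <- function(hotspots, occupancy = 0.5,
                          residues = NULL, box = c(40, 40, 40), seed = NULL) {
  hotspots <- as_points(hotspots, allow_empty = FALSE, what = "hotspots")
  n <- nrow(hotspots)
  occupancy <- rep_len(as.numeric(occupancy), n)
  if (any(!is.finite(occupancy)) || any(occupancy <= 0) || any(occupancy > 1))
    stop_config("'occupancy' must lie in (0, 1]")
  if (is.null(residues))
    residues <- rep(list(list(resname = "ASP", offset = NULL)), n)
  if (length(residues) != n)
    stop_config("'residues' must have one entry per hotspot")
  scheme <- residue_type_scheme()
  for (r in residues) {
    ty <- classify_residue(r$resname, scheme)
    if (ty == "excluded")
      stop_config("planted residue '%s' is excluded from the typing scheme",
                  r$resname)
  }
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop_config("'box' must be 3 positive lengths")
  structure(list(hotspots = hotspots, occupancy = occupancy,
                 residues = residues, box = box, seed = seed),
            class = "planted_truth")
}

build_planted_residue <- function(resname, cb_pos, direction, chain, resno) {
  u <- direction / sqrt(sum(direction^2))
  # any vector not parallel to u gives a perpendicular basis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  p <- ref - sum(ref * u) * u
  p <- p / sqrt(sum(p^2))
  q <- c(u[2] * p[3] - u[3] * p[2], u[3] * p[1] - u[1] * p[3],
         u[1] * p[2] - u[2] * p[1])
  ca <- cb_pos + 1.53 * u
  ra <- residue_atoms_local(resname, ca, -u, p, q)  # CB points back to cb_pos
  atom_table(name = ra$names, resname = resname, chain = chain, resno = resno,
             coords = ra$coords, element = ra$elements)
}

#' Generate a synthetic mixed-solvent trajectory with planted hotspots
#'
#' Emulates the sampling regime the occupancy analysis assumes: each frame,
#' hotspot-designated probe copies sit on their hotspot with the stated
#' occupancy probability -- anchored by the probe's first alignment atom at
#' the hotspot center, with isotropic Gaussian jitter and a random
#' symmetry-equivalent atom relabeling -- and otherwise (like all remaining
#' copies) are placed uniformly in the box away from the protein, in a
#' random orientation.  A residue of the declared type is planted with its
#' C-beta at the declared offset from each hotspot.  The protein is rigid
#' across frames.
#'
#' @param protein Protein atom table (e.g. [generate_toy_protein()]).
#' @param truth A [planted_truth()].
#' @param n_frames Number of snapshots (>= 1).
#' @param timestep Time between snapshots in ps (default 10).
#' @param probe Probe template: a [probe_definition()] with coordinates
#'   (default [toy_probe_template()]).
#' @param n_probes Total probe copies per frame (default 5); the first
#'   `nrow(truth$hotspots)` copies are the hotspot visitors.
#' @param run_id Run identifier.
#' @param seed Optional RNG seed.
#' @param jitter Isotropic positional noise sigma in Angstrom at the
#'   hotspot (default 0.3).
#' @param clearance Minimum distance of bulk probe atoms from protein heavy
#'   atoms in Angstrom (default 6, i.e. outside the 5 Angstrom shell).
#' @return A list with `trajectory` and `truth`; the truth gains
#'   `expected_cb_ref`, the reference-probe-frame position each planted
#'   C-beta maps to under a correct analysis.
#' @export
generate_msmd_trajectory <- function(protein, truth, n_frames = 200,
                                     timestep = 10,
                                     probe = toy_probe_template(),
                                     n_probes = 5, run_id = 1, seed = NULL,
                                     jitter = 0.3, clearance = 6) {
  if (!inherits(truth, "planted_truth")) stop_config("'truth' must be a planted_truth")
  if (!inherits(probe, "probe_definition") || is.null(probe$coords))
    stop_config("'probe' must be a probe_definition with coordinates")
  if (!is.numeric(n_frames) || n_frames < 1) stop_config("'n_frames' must be >= 1")
  n_hot <- nrow(truth$hotspots)
  if (n_probes < n_hot)
    stop_config("'n_probes' (%d) must cover the %d hotspot(s)", n_probes, n_hot)
  if (!is.null(seed)) set.seed(seed)
  if (!all(rownames(probe$coords) %in% probe$alignment_atoms))
    stop_config("generator requires every probe template atom to be an alignment atom")

  anchor <- probe$alignment_atoms[1L]
  anchor_xyz <- probe$coords[anchor, ]
  centroid <- colMeans(probe$coords)
  # documented default: planted C-beta 3 A from the probe centroid along
  # the probe frame's x (symmetry) axis
  default_offset <- centroid + c(-3, 0, 0) - anchor_xyz

  expected_cb_ref <- vector("list", n_hot)
  planted_rows <- vector("list", n_hot)
  n_prot_res <- max(protein$resno)
  for (h in seq_len(n_hot)) {
    off <- truth$residues[[h]]$offset %||% default_offset
    truth$residues[[h]]$offset <- off
    cb <- truth$hotspots[h, ] + off
    planted_rows[[h]] <- build_planted_residue(
      truth$residues[[h]]$resname, cb, off, chain = "A",
      resno = n_prot_res + h)
    expected_cb_ref[[h]] <- as.numeric(anchor_xyz + off)
  }
  truth$expected_cb_ref <- expected_cb_ref
  full_protein <- rbind(protein, do.call(rbind, planted_rows))
  prot_heavy <- as.matrix(
    full_protein[full_protein$heavy, c("x", "y", "z"), drop = FALSE])

  tmpl_site <- sweep(probe$coords, 2L, anchor_xyz)       # anchor at origin
  tmpl_bulk <- sweep(probe$coords, 2L, centroid)          # centroid at origin
  atom_names <- rownames(probe$coords)
  elements <- probe$elements %||% rep("C", nrow(probe$coords))
  box <- truth$box
  n_sym <- length(probe$symmetry_mappings)

  place_bulk <- function() {
    for (a in 1:1000) {
      ctr <- stats::runif(3) * box
      xyz <- sweep(tmpl_bulk %*% t(random_rotation()), 2L, ctr, "+")
      d2min <- Inf
      for (i in seq_len(nrow(xyz))) {
        dd <- (prot_heavy[, 1] - xyz[i, 1])^2 + (prot_heavy[, 2] - xyz[i, 2])^2 +
          (prot_heavy[, 3] - xyz[i, 3])^2
        d2min <- min(d2min, min(dd))
      }
      if (d2min >= clearance^2) return(xyz)
    }
    stop_data("could not place a bulk probe away from the protein")
  }

  snaps <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    probe_rows <- vector("list", n_probes)
    for (j in seq_len(n_probes)) {
      visiting <- j <= n_hot && stats::runif(1) < truth$occupancy[j]
      if (visiting) {
        # atom set sits on the fixed hotspot sites; a random symmetry
        # mapping relabels which atom occupies which site
        m <- probe$symmetry_mappings[[sample.int(n_sym, 1L)]]
        sites <- sweep(tmpl_site[probe$alignment_atoms, , drop = FALSE],
                       2L, truth$hotspots[j, ], "+")
        xyz <- sites[match(atom_names, m), , drop = FALSE]
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter),
                            ncol = 3L)
      } else {
        xyz <- place_bulk()
      }
      probe_rows[[j]] <- atom_table(
        name = atom_names, resname = probe$resname, chain = "X",
        resno = 900L + j, coords = xyz,
        element = elements[match(atom_names, rownames(probe$coords))],
        record = "HETATM", is_probe = TRUE,
        probe_id = paste0("X:", 900L + j))
    }
    snaps[[f]] <- snapshot(time = f * timestep,
                           atoms = rbind(full_protein,
                                         do.call(rbind, probe_rows)),
                           box = box)
  }
  list(trajectory = trajectory(run_id = run_id, snapshots = snaps,
                               timestep = timestep),
       truth = truth)
}

#' Reference synthetic configuration
#'
#' The documented desk-scale configuration under which the full pipeline is
#' expected to recover the planted truth: 20 pseudo-independent runs of 200
#' frames, 5 probe copies, one hotspot at occupancy 0.5, surface threshold
#' 0.2.  The hotspot is placed 6 Angstrom off the protein's +x face on a
#' half-integer lattice point, i.e. at a voxel center of the snapped
#' analysis grid.
#'
#' @return A named list of generator and analysis parameters.
#' @export
reference_synthetic_config <- function() {
  list(n_runs = 20L, n_frames = 200L, n_probes = 5L, n_residues = 30L,
       occupancy = 0.5, box = c(40, 40, 40), theta = 0.2,
       shell_cutoff = 5, environment_cutoff = 4, jitter = 0.3,
       clearance = 6, timestep = 10)
}

#' Generate the reference batch of synthetic runs
#'
#' Builds one shared toy protein and planted truth, then the requested
#' number of pseudo-independent runs (different probe placement RNG streams,
#' same protein and hotspot), per the
#' [reference_synthetic_config()] defaults.
#'
#' @param seed Master seed; per-run seeds are derived from it.
#' @param n_runs,n_frames,n_probes,occupancy Overrides of the reference
#'   configuration.
#' @param probe Probe template (default [toy_probe_template()]).
#' @return A list with `trajectories` (list of [trajectory()]),
#'   `truth`, `protein` and `config`.
#' @export
generate_reference_runs <- function(seed = 1, n_runs = NULL, n_frames = NULL,
                                    n_probes = NULL, occupancy = NULL,
                                    probe = toy_probe_template()) {
  cfg <- reference_synthetic_config()
  cfg$n_runs <- as.integer(n_runs %||% cfg$n_runs)
  cfg$n_frames <- as.integer(n_frames %||% cfg$n_frames)
  cfg$n_probes <- as.integer(n_probes %||% cfg$n_probes)
  cfg$occupancy <- occupancy %||% cfg$occupancy

  protein <- generate_toy_protein(cfg$n_residues, seed = seed)
  # center the fold in the box with an integer shift (preserves the
  # half-integer voxel-center lattice)
  xyz <- as.matrix(protein[, c("x", "y", "z")])
  shift <- round(cfg$box / 2 - colMeans(xyz))
  protein[, c("x", "y", "z")] <- sweep(xyz, 2L, shift, "+")
  hx <- floor(max(protein$x[protein$heavy]) + 6) + 0.5
  hotspot <- c(hx, floor(cfg$box[2] / 2) + 0.5, floor(cfg$box[3] / 2) + 0.5)
  truth <- planted_truth(hotspot, occupancy = cfg$occupancy, box = cfg$box,
                         seed = seed)

  trajs <- vector("list", cfg$n_runs)
  for (k in seq_len(cfg$n_runs)) {
    run_seed <- (seed * 1009L + 97L * k) %% .Machine$integer.max
    gen <- generate_msmd_trajectory(protein, truth, n_frames = cfg$n_frames,
                                    timestep = cfg$timestep, probe = probe,
                                    n_probes = cfg$n_probes,
                                    run_id = sprintf("run%02d", k),
                                    seed = run_seed, jitter = cfg$jitter,
                                    clearance = cfg$clearance)
    trajs[[k]] <- gen$trajectory
    truth <- gen$truth
  }
  list(trajectories = trajs, truth = truth, protein = protein, config = cfg)
}
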