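# PMAP / max-PMAP / preferable surface: the occupancy-map stage of the
# pipeline.  A PMAP is the normalized voxel occupancy of probe heavy atoms
# restricted to the 5 A shell around the protein; the max-PMAP keeps, per
# voxel, the largest value across independent runs; the preferable surface
# is the voxel set at or above a threshold of the max-PMAP.

#' Compute the probe occupancy probability map (PMAP) of one run
#'
#' Bins every probe heavy atom of every snapshot into the voxel grid,
#' discards voxels outside the surface shell `V` (voxels whose center is
#' within `shell_cutoff` of a protein heavy atom of the reference snapshot),
#' and scales the remaining values so they sum to 1.0.
#'
#' The trajectory is expected to be fitted to the common reference frame
#' already (see [fit_protein_to_reference()]).
#'
#' @param traj A fitted [trajectory()].
#' @param grid Grid geometry as a [grid3d()]; defaults to the protein heavy
#'   atoms' bounding box of the first snapshot plus `margin`.
#' @param mask Precomputed shell [mask_within_distance()]; pass one shared
#'   mask when several runs must be combinable into a max-PMAP.  Defaults to
#'   the shell of the first snapshot's protein heavy atoms.
#' @param shell_cutoff Shell radius in Angstrom (default 5).
#' @param margin Grid margin in Angstrom when `grid` is derived (default 8).
#' @return An object of class `pmap`: list with `grid` (normalized values),
#'   `mask`, `run_id`, `probe_resname`, `n_frames`, `n_binned`,
#'   `n_out_of_bounds`.
#' @export
compute_pmap <- function(traj, grid = NULL, mask = NULL, shell_cutoff = 5,
                         margin = 8) {
  if (!inherits(traj, "trajectory")) stop_data("'traj' must be a trajectory")
  check_scalar_number(shell_cutoff, "shell_cutoff", positive = TRUE)
  ref <- traj$snapshots[[1L]]
  prot_xyz <- as.matrix(protein_atoms(ref, heavy_only = TRUE)[, c("x", "y", "z")])
  if (is.null(grid)) grid <- grid_from_points(prot_xyz, margin = margin)
  assert_grid(grid)
  if (is.null(mask)) mask <- mask_within_distance(grid, prot_xyz, shell_cutoff)
  assert_mask(mask, grid)

  pts <- do.call(rbind, lapply(traj$snapshots, function(s) {
    a <- s$atoms
    as.matrix(a[a$is_probe & a$heavy, c("x", "y", "z"), drop = FALSE])
  }))
  counts <- bin_points(grid, pts)
  normed <- normalize_masked(counts, mask)
  structure(
    list(grid = normed, mask = mask, run_id = traj$run_id,
         probe_resname = unique(ref$atoms$resname[ref$atoms$is_probe])[1L],
         n_frames = length(traj$snapshots), n_binned = nrow(pts),
         n_out_of_bounds = attr(counts, "out_of_bounds")),
    class = "pmap"
  )
}

#' @export
print.pmap <- function(x, ...) {
  cat(sprintf("pmap (run '%s', probe %s): %d frames, shell sum %.9f, max %.4f\n",
              as.character(x$run_id), x$probe_resname, x$n_frames,
              sum(x$grid$values[x$mask$member]), max(x$grid$values)))
  invisible(x)
}

#' Combine PMAPs of independent runs into a max-PMAP
#'
#' Stores, for each voxel of the shared shell, the largest PMAP value across
#' the runs.  This compensates the under-sampling of deep pockets that
#' probes rarely reach: a single binding event in one run is enough to mark
#' the voxel.  The shell sum of the result is >= 1.0 (and <= the number of
#' runs), even though each input is a probability map.
#'
#' @param pmaps List of [compute_pmap()] results on one shared grid and mask.
#' @return An object of class `max_pmap`: list with `grid`, `mask`,
#'   `n_runs`.
#' @export
compute_max_pmap <- function(pmaps) {
  if (inherits(pmaps, "pmap")) pmaps <- list(pmaps)
  if (!is.list(pmaps) || length(pmaps) < 1L ||
      !all(vapply(pmaps, inherits, logical(1), "pmap")))
    stop_config("'pmaps' must be a non-empty list of pmap objects")
  ref <- pmaps[[1L]]
  for (p in pmaps[-1L]) {
    if (!same_geometry(ref$grid, p$grid))
      stop_data("geometry mismatch among PMAPs")
    if (!identical(ref$mask$member, p$mask$member))
      stop_data("mask mismatch among PMAPs (shells must be shared)")
  }
  structure(
    list(grid = voxelwise_max(lapply(pmaps, `[[`, "grid")),
         mask = ref$mask, n_runs = length(pmaps)),
    class = "max_pmap"
  )
}

#' @export
print.max_pmap <- function(x, ...) {
  cat(sprintf("max_pmap: %d runs, shell sum %.4f, max %.4f\n", x$n_runs,
              sum(x$grid$values[x$mask$member]), max(x$grid$values)))
  invisible(x)
}

#' Preferable protein surface of a probe
#'
#' Voxels whose max-PMAP value is equal to or greater than `theta`
#' (inclusive).  An empty surface is legal and reported with a warning so
#' threshold sweeps stay scriptable.
#'
#' @param max_pmap A [compute_max_pmap()] result (a single `pmap` is also
#'   accepted).
#' @param theta Threshold on the max-PMAP value (default 0.2).
#' @return An object of class `preferable_surface`: list with `voxels`
#'   (data frame `i`, `j`, `k`, `value`), `member` (logical array), `theta`
#'   and the grid geometry (`origin`, `shape`, `spacing`).
#' @export
preferable_surface <- function(max_pmap, theta = 0.2) {
  if (!inherits(max_pmap, c("max_pmap", "pmap")))
    stop_config("'max_pmap' must be a max_pmap (or pmap) object")
  check_scalar_number(theta, "theta")
  grid <- max_pmap$grid
  member <- grid$values >= theta & max_pmap$mask$member
  vox <- threshold_voxels(grid, theta)
  keep <- max_pmap$mask$member[cbind(vox$i, vox$j, vox$k)]
  vox <- vox[keep, , drop = FALSE]
  rownames(vox) <- NULL
  if (nrow(vox) == 0L)
    warnf("preferable surface is empty at theta = %g (max value %.4f)",
          theta, max(grid$values))
  structure(
    list(voxels = vox, member = member, theta = as.numeric(theta),
         origin = grid$origin, shape = grid$shape, spacing = grid$spacing),
    class = "preferable_surface"
  )
}

#' @export
print.preferable_surface <- function(x, ...) {
  cat(sprintf("preferable_surface: %d voxels at theta >= %g\n",
              nrow(x$voxels), x$theta))
  invisible(x)
}

#' Write a preferable surface as TSV (and optional pseudo-PDB)
#'
#' The TSV holds the 1-based voxel indices and the max-PMAP value; the
#' pseudo-PDB contains one dummy atom per voxel center for quick visual
#' checks in a molecular viewer.
#'
#' @param surface A [preferable_surface()].
#' @param path Output TSV path.
#' @param pdb_path Optional pseudo-PDB path.
#' @return `path`, invisibly.
#' @export
write_surface_table <- function(surface, path, pdb_path = NULL) {
  if (!inherits(surface, "preferable_surface"))
    stop_config("'surface' must be a preferable_surface")
  utils::write.table(surface$voxels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pdb_path)) {
    g <- grid3d(surface$origin, surface$shape, surface$spacing)
    ctr <- voxel_centers(g, as.matrix(surface$voxels[, c("i", "j", "k")]))
    lines <- pdb_atom_line("HETATM", seq_len(nrow(ctr)), "DU", "SUR", "S",
                           seq_len(nrow(ctr)), ctr[, 1], ctr[, 2], ctr[, 3], "X")
    writeLines(c(lines, "END"), pdb_path)
  }
  invisible(path)
}
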