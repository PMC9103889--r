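# Residue interaction profile: per-residue-type count grids of C-beta (or
# any selected side-chain atom) around the reference probe, aggregated over
# all extracted residue environments.

#' Grid geometry of an interaction profile
#'
#' A cube of `+/- half_extent` Angstrom around the reference probe's
#' heavy-atom centroid, with voxel centers on the integer offsets from the
#' centroid.
#'
#' @param reference_probe A [probe_definition()] with coordinates.
#' @param half_extent Half edge length in Angstrom (default 8).
#' @param spacing Voxel size in Angstrom (default 1).
#' @return An all-zero [grid3d()].
#' @export
profile_grid <- function(reference_probe, half_extent = 8, spacing = 1) {
  if (!inherits(reference_probe, "probe_definition") ||
      is.null(reference_probe$coords))
    stop_config("'reference_probe' must be a probe_definition with coordinates")
  check_scalar_number(half_extent, "half_extent", positive = TRUE)
  check_scalar_number(spacing, "spacing", positive = TRUE)
  centroid <- colMeans(reference_probe$coords)
  n <- 2 * ceiling(half_extent / spacing) + 1
  grid3d(centroid - (n / 2) * spacing, rep(n, 3L), spacing)
}

#' Build the residue interaction profile
#'
#' For each environment, the selected atom (default `CB`) of each
#' surrounding residue is binned into the count grid of that residue's type.
#' Residues classified `"excluded"` (glycine) or lacking the selected atom
#' are counted in the skip metadata; selected atoms falling outside the
#' profile grid are counted but not binned.
#'
#' @param environments A [extract_environments()] result (non-empty).
#' @param reference_probe The [probe_definition()] the environments were
#'   aligned to.
#' @param grid Profile grid geometry; defaults to [profile_grid()] of the
#'   reference probe.
#' @param atom_selector Name of the atom to bin (default `"CB"`).
#' @param scheme A [residue_type_scheme()].
#' @param on_unknown Passed to [classify_residue()] (default `"exclude"`:
#'   unknown residue codes are skipped with a warning).
#' @return An object of class `interaction_profile`: list with `grids` (one
#'   count [grid3d()] per residue type), `counts` (in-bounds counts per
#'   type), `n_environments`, `atom_selector`, `skipped` (list with
#'   `excluded`, `no_atom`, `out_of_bounds`), and `reference_probe`.
#' @export
build_profile <- function(environments, reference_probe, grid = NULL,
                          atom_selector = "CB",
                          scheme = residue_type_scheme(),
                          on_unknown = "exclude") {
  if (!inherits(environments, "residue_environment_set") || length(environments) == 0L)
    stop_data("'environments' must be a non-empty residue_environment_set")
  if (!is.character(atom_selector) || length(atom_selector) != 1L ||
      !nzchar(atom_selector))
    stop_config("'atom_selector' must be a single atom name")
  if (is.null(grid)) grid <- profile_grid(reference_probe)
  assert_grid(grid)

  pts <- stats::setNames(vector("list", length(RESIDUE_TYPES)), RESIDUE_TYPES)
  n_excluded <- 0L
  n_no_atom <- 0L
  for (env in environments) {
    if (nrow(env$residues) == 0L) next
    types <- classify_residue(env$residues$resname, scheme,
                              on_unknown = on_unknown)
    for (r in seq_along(types)) {
      ty <- types[r]
      if (ty == "excluded") { n_excluded <- n_excluded + 1L; next }
      ra <- env$residue_atoms[[r]]
      sel <- ra[ra$name == atom_selector, , drop = FALSE]
      if (nrow(sel) == 0L) { n_no_atom <- n_no_atom + 1L; next }
      pts[[ty]][[length(pts[[ty]]) + 1L]] <-
        c(sel$x[1L], sel$y[1L], sel$z[1L])
    }
  }
  grids <- list()
  counts <- stats::setNames(numeric(length(RESIDUE_TYPES)), RESIDUE_TYPES)
  n_oob <- 0L
  for (ty in RESIDUE_TYPES) {
    g <- grid
    if (length(pts[[ty]])) {
      g <- bin_points(grid, do.call(rbind, pts[[ty]]))
      n_oob <- n_oob + attr(g, "out_of_bounds")
    }
    grids[[ty]] <- g
    counts[[ty]] <- sum(g$values)
  }
  structure(
    list(grids = grids, counts = counts, n_environments = length(environments),
         atom_selector = atom_selector,
         skipped = list(excluded = n_excluded, no_atom = n_no_atom,
                        out_of_bounds = n_oob),
         reference_probe = reference_probe),
    class = "interaction_profile"
  )
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf("interaction_profile: %d environments, '%s' atoms binned\n",
              x$n_environments, x$atom_selector))
  for (ty in names(x$counts))
    cat(sprintf("  %-12s %6d\n", ty, as.integer(x$counts[[ty]])))
  cat(sprintf("  skipped: %d excluded-type, %d without the atom, %d out of grid\n",
              x$skipped$excluded, x$skipped$no_atom, x$skipped$out_of_bounds))
  invisible(x)
}

#' Write an interaction profile to disk
#'
#' One OpenDX grid per residue type (`profile_<type><suffix>.dx`), a
#' reference-probe PDB for superposition in viewers, and a TSV aggregation
#' report.
#'
#' @param profile An [build_profile()] result.
#' @param dir Output directory (created if needed).
#' @param suffix Suffix inserted before `.dx` (e.g. `"_stable"`).
#' @return The directory, invisibly.
#' @export
write_profile <- function(profile, dir, suffix = "") {
  if (!inherits(profile, "interaction_profile"))
    stop_config("'profile' must be an interaction_profile")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ty in names(profile$grids))
    write_dx(profile$grids[[ty]],
             file.path(dir, sprintf("profile_%s%s.dx", ty, suffix)))
  rp <- profile$reference_probe
  if (!is.null(rp$coords)) {
    lines <- pdb_atom_line("HETATM", seq_len(nrow(rp$coords)),
                           rownames(rp$coords), rp$resname, "P", 1,
                           rp$coords[, 1], rp$coords[, 2], rp$coords[, 3],
                           rp$elements %||% "C")
    writeLines(c(lines, "END"),
               file.path(dir, sprintf("reference_probe%s.pdb", suffix)))
  }
  rep_df <- data.frame(type = names(profile$counts),
                       binned = as.integer(profile$counts))
  utils::write.table(rep_df, file.path(dir, sprintf("profile_report%s.tsv", suffix)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
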