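# End-to-end pipeline: fit -> per-run PMAP -> max-PMAP -> preferable
# surface -> residue environments -> interaction profile -> optional
# stability filter, with a JSON manifest so runs are auditable.

#' Run the full analysis pipeline
#'
#' Input trajectories come either from `config$runs$paths` (multi-model PDB
#' files, one per run) or, when `trajectories` is given, from memory; with
#' neither, `config$runs$count` synthetic runs are generated from the
#' planted-hotspot generator.  All runs are rigidly fitted to a shared
#' reference frame (the first run's first snapshot; optionally its
#' principal-axes canonical frame), mapped on one shared grid and shell.
#'
#' @param config A `run_config` (see [load_validate_config()]).
#' @param output_dir Directory for DX/TSV/JSON artifacts; `NULL` skips all
#'   file output.
#' @param trajectories Optional list of [trajectory()] objects overriding
#'   file/synthetic input.
#' @return Invisibly, a list with `pmaps`, `max_pmap`, `surface`,
#'   `environments`, `profile`, `filtered` (when the stability filter is
#'   on), `truth` (synthetic mode), and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         trajectories = NULL) {
  cfg <- validate_config(unclass(config))
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  probe_def <- config_probe(cfg)
  if (is.null(trajectories)) {
    if (length(cfg$runs$paths)) {
      for (p in cfg$runs$paths)
        if (!file.exists(p)) stop_data("missing trajectory for run: %s", p)
      trajectories <- lapply(seq_along(cfg$runs$paths), function(k)
        read_multimodel_pdb(cfg$runs$paths[k], cfg$probe$resname,
                            run_id = sprintf("run%02d", k),
                            timestep = cfg$schedule$interval))
    } else {
      gen <- generate_reference_runs(seed = cfg$seed,
                                     n_runs = cfg$runs$count,
                                     n_frames = cfg$synthetic$n_frames,
                                     n_probes = cfg$synthetic$n_probes,
                                     occupancy = cfg$synthetic$occupancy,
                                     probe = probe_def)
      trajectories <- gen$trajectories
      truth <- gen$truth
    }
  }

  # stage: fit all runs to one shared reference frame
  reference <- trajectories[[1L]]$snapshots[[1L]]
  trajectories <- lapply(trajectories, fit_protein_to_reference,
                         reference = reference,
                         canonicalize = isTRUE(cfg$canonical_frame))

  # shared grid and shell from the fitted reference
  ref_fit <- trajectories[[1L]]$snapshots[[1L]]
  prot_xyz <- as.matrix(
    protein_atoms(ref_fit, heavy_only = TRUE)[, c("x", "y", "z")])
  grid <- grid_from_points(prot_xyz, margin = cfg$grid$margin,
                           spacing = cfg$grid$spacing,
                           snap = isTRUE(cfg$grid$snap))
  mask <- mask_within_distance(grid, prot_xyz, cfg$thresholds$shell_cutoff)

  pmaps <- lapply(trajectories, compute_pmap, grid = grid, mask = mask,
                  shell_cutoff = cfg$thresholds$shell_cutoff)
  if (!is.null(output_dir)) {
    shell_grid <- grid
    shell_grid$values <- array(as.numeric(mask$member), dim = grid$shape)
    write_dx(shell_grid, file.path(output_dir, "shell.dx"))
    for (k in seq_along(pmaps))
      write_dx(pmaps[[k]]$grid,
               file.path(output_dir, sprintf("pmap_run%02d.dx", k)))
  }

  mp <- compute_max_pmap(pmaps)
  surface <- preferable_surface(mp, theta = cfg$thresholds$surface_theta)
  if (!is.null(output_dir)) {
    write_dx(mp$grid, file.path(output_dir, "max_pmap.dx"))
    write_surface_table(surface, file.path(output_dir, "surface.tsv"),
                        pdb_path = file.path(output_dir, "surface_centers.pdb"))
  }

  env_sets <- lapply(trajectories, extract_environments, surface = surface,
                     reference_probe = probe_def,
                     cutoff = cfg$thresholds$environment_cutoff,
                     rule = cfg$detection_rule)
  environments <- combine_environments(env_sets)

  profile <- NULL
  if (length(environments) > 0L) {
    grid_p <- profile_grid(probe_def, half_extent = cfg$profile$half_extent,
                           spacing = cfg$grid$spacing)
    profile <- build_profile(environments, probe_def, grid = grid_p,
                             atom_selector = cfg$profile$atom_selector)
    if (!is.null(output_dir)) write_profile(profile, output_dir)
  } else warnf("no residue environments extracted; profile skipped")

  filtered <- NULL
  if (isTRUE(cfg$stability_filter) && length(environments) > 0L) {
    verdicts <- do.call(rbind, lapply(trajectories, stable_mask,
                                      lag = cfg$thresholds$stability_lag,
                                      cutoff = cfg$thresholds$stability_cutoff))
    filtered <- filter_environments(environments, verdicts)
    if (length(filtered$environments) > 0L) {
      grid_p <- profile_grid(probe_def, half_extent = cfg$profile$half_extent,
                             spacing = cfg$grid$spacing)
      filtered$profile <- build_profile(filtered$environments, probe_def,
                                        grid = grid_p,
                                        atom_selector = cfg$profile$atom_selector)
      if (!is.null(output_dir))
        write_profile(filtered$profile, output_dir, suffix = "_stable")
    }
    if (!is.null(output_dir))
      utils::write.table(
        data.frame(removed_fraction = filtered$removed_fraction,
                   n_input = filtered$n_input, n_kept = filtered$n_kept,
                   n_undefined = filtered$n_undefined),
        file.path(output_dir, "removed_fractions.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("probemap")),
    parameters = cfg,
    n_runs = length(trajectories),
    n_frames = vapply(trajectories, function(t) length(t$snapshots), integer(1)),
    shell_voxels = sum(mask$member),
    surface_voxels = nrow(surface$voxels),
    n_environments = length(environments),
    n_poses_checked = attr(environments, "n_checked"),
    profile_counts = if (!is.null(profile)) as.list(profile$counts) else NULL,
    stability = if (!is.null(filtered))
      list(removed_fraction = filtered$removed_fraction,
           n_kept = filtered$n_kept,
           n_undefined = filtered$n_undefined) else NULL
  )
  if (!is.null(output_dir))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(trajectories = trajectories, grid = grid, mask = mask,
                 pmaps = pmaps, max_pmap = mp, surface = surface,
                 environments = environments, profile = profile,
                 filtered = filtered, truth = truth, manifest = manifest))
}
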