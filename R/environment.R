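# Residue-environment extraction: detect probes sitting on the preferable
# surface, collect the residues in contact (4 A heavy-atom criterion), and
# map each probe pose plus its surroundings into the reference probe frame
# with a symmetry-aware least-squares superposition.

#' Is a probe pose on the preferable surface?
#'
#' Detection rule (configurable): `"any"` (default) requires at least one
#' probe heavy atom inside a member voxel, `"centroid"` tests the heavy-atom
#' centroid, `"all"` requires every heavy atom inside.
#'
#' @param probe Probe atom table (see [probe_atoms()]) or an `n x 3`
#'   coordinate matrix of heavy atoms.
#' @param surface A [preferable_surface()].
#' @param rule Detection rule.
#' @return Logical scalar.
#' @export
probe_on_surface <- function(probe, surface,
                             rule = c("any", "centroid", "all")) {
  rule <- match.arg(rule)
  if (!inherits(surface, "preferable_surface"))
    stop_config("'surface' must be a preferable_surface")
  if (is.data.frame(probe))
    probe <- as.matrix(probe[probe$heavy, c("x", "y", "z"), drop = FALSE])
  probe <- as_points(probe, allow_empty = FALSE, what = "probe")
  if (rule == "centroid") probe <- matrix(colMeans(probe), nrow = 1L)
  g <- grid3d(surface$origin, surface$shape, surface$spacing)
  idx <- voxel_of(g, probe)
  ok <- !is.na(idx[, 1L])
  hit <- logical(nrow(probe))
  hit[ok] <- surface$member[idx[ok, , drop = FALSE]]
  switch(rule, any = any(hit), centroid = hit[1L], all = all(hit))
}

#' Residues in contact with a probe pose
#'
#' Returns the residues with at least one heavy atom within `cutoff`
#' (inclusive) of any probe heavy atom, in the original coordinates.
#'
#' @param probe Probe atom table or heavy-atom coordinate matrix.
#' @param protein Protein atom table.
#' @param cutoff Contact cutoff in Angstrom (default 4, inclusive).
#' @return Data frame of contacting residues: `chain`, `resno`, `resname`,
#'   `min_dist`.
#' @export
residues_within <- function(probe, protein, cutoff = 4) {
  check_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (is.data.frame(probe))
    probe <- as.matrix(probe[probe$heavy, c("x", "y", "z"), drop = FALSE])
  probe <- as_points(probe, allow_empty = FALSE, what = "probe")
  prot <- protein[protein$heavy, , drop = FALSE]
  if (nrow(prot) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), min_dist = numeric(0)))
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  # distance of every protein heavy atom to its nearest probe heavy atom
  d2 <- rep(Inf, nrow(pxyz))
  for (a in seq_len(nrow(probe))) {
    dd <- (pxyz[, 1] - probe[a, 1])^2 + (pxyz[, 2] - probe[a, 2])^2 +
      (pxyz[, 3] - probe[a, 3])^2
    d2 <- pmin(d2, dd)
  }
  key <- paste(prot$chain, prot$resno, sep = ":")
  min_by_res <- tapply(d2, key, min)
  hit_keys <- names(min_by_res)[sqrt(min_by_res) <= cutoff]
  if (!length(hit_keys))
    return(data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), min_dist = numeric(0)))
  first <- match(hit_keys, key)
  out <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                    resname = prot$resname[first],
                    min_dist = sqrt(as.numeric(min_by_res[hit_keys])),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Superpose a probe pose onto the reference probe
#'
#' Least-squares rigid superposition (proper rotation + translation) of the
#' designated alignment atoms, computed once per symmetry-equivalent atom
#' mapping; the mapping with the minimal RMSD wins.  This removes the
#' spurious RMSD a symmetric probe (e.g. a benzene ring rotated by 60
#' degrees) would otherwise show.
#'
#' @param mobile Observed probe coordinates: `n x 3` matrix with atom names
#'   as row names, or a probe atom table.
#' @param reference Reference probe coordinates (same conventions).
#' @param alignment_atoms Ordered atom names used for the fit.
#' @param symmetry_mappings List of permutations of `alignment_atoms`.
#' @return A list with `rotation`, `translation`, `rmsd` (Angstrom) and
#'   `mapping` (the winning permutation).
#' @export
superpose_probe <- function(mobile, reference, alignment_atoms,
                            symmetry_mappings = list(alignment_atoms)) {
  named_coords <- function(x, what) {
    if (is.data.frame(x)) x <- coords_of(x)
    x <- as_points(x, allow_empty = FALSE, what = what)
    if (is.null(rownames(x)))
      stop_config("'%s' must carry atom names as row names", what)
    x
  }
  mobile <- named_coords(mobile, "mobile")
  reference <- named_coords(reference, "reference")
  alignment_atoms <- as.character(alignment_atoms)
  missing_ref <- setdiff(alignment_atoms, rownames(reference))
  if (length(missing_ref))
    stop_data("reference lacks alignment atom(s): %s",
              paste(missing_ref, collapse = ", "))
  ref_xyz <- reference[alignment_atoms, , drop = FALSE]
  best <- NULL
  for (m in symmetry_mappings) {
    m <- as.character(m)
    if (!setequal(m, alignment_atoms))
      stop_config("symmetry mapping (%s) is not a permutation of the alignment atoms",
                  paste(m, collapse = ", "))
    missing_mob <- setdiff(m, rownames(mobile))
    if (length(missing_mob))
      stop_data("mobile probe lacks alignment atom(s): %s",
                paste(missing_mob, collapse = ", "))
    fit <- kabsch(mobile[m, , drop = FALSE], ref_xyz)
    # tolerance tie-break: planar (e.g. any 3-atom) alignment sets make
    # mirror-related mappings exactly degenerate in RMSD, so an exact "<"
    # would pick the winner by floating-point noise.  Prefer the earliest
    # listed mapping unless a later one is better beyond noise.
    if (is.null(best) || fit$rmsd < best$rmsd - 1e-6) {
      best <- fit
      best$mapping <- m
    }
  }
  best
}

#' Extract residue environments of surface-bound probe poses
#'
#' For every snapshot and every probe copy whose pose passes the on-surface
#' gate, collects the residues in contact (in the original coordinates),
#' superposes the probe onto the reference probe (minimum-RMSD symmetry
#' mapping), and expresses probe and residues in the reference probe frame.
#' Poses whose superposition fails (degenerate geometry) are skipped and
#' counted, not fatal.
#'
#' @param traj A fitted [trajectory()] in the same frame as `surface`.
#' @param surface A [preferable_surface()].
#' @param reference_probe A [probe_definition()] with reference coordinates.
#' @param cutoff Contact cutoff in Angstrom (default 4).
#' @param rule On-surface detection rule (see [probe_on_surface()]).
#' @return A list of environments (class `residue_environment_set`); each
#'   element holds `run_id`, `time`, `probe_id`, `probe` (atom table in the
#'   reference frame), `residues` (contact table with a `coords` atom table
#'   attached per residue), and `rmsd`.  Attributes report `n_checked` and
#'   `n_skipped`.
#' @export
extract_environments <- function(traj, surface, reference_probe, cutoff = 4,
                                 rule = "any") {
  if (!inherits(traj, "trajectory")) stop_data("'traj' must be a trajectory")
  if (!inherits(reference_probe, "probe_definition") ||
      is.null(reference_probe$coords))
    stop_config("'reference_probe' must be a probe_definition with coordinates")
  envs <- list()
  n_checked <- 0L
  n_skipped <- 0L
  for (snap in traj$snapshots) {
    prot <- protein_atoms(snap)
    for (pr in probe_atoms(snap)) {
      n_checked <- n_checked + 1L
      heavy <- pr[pr$heavy, , drop = FALSE]
      if (nrow(heavy) == 0L) next
      if (!probe_on_surface(heavy, surface, rule = rule)) next
      contacts <- residues_within(heavy, prot, cutoff = cutoff)
      fit <- tryCatch(
        superpose_probe(heavy, reference_probe$coords,
                        reference_probe$alignment_atoms,
                        reference_probe$symmetry_mappings),
        error = function(e) NULL)
      if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
      pr_t <- pr
      xyz <- apply_rigid(as.matrix(pr[, c("x", "y", "z")]),
                         fit$rotation, fit$translation)
      pr_t$x <- xyz[, 1]; pr_t$y <- xyz[, 2]; pr_t$z <- xyz[, 3]
      res_list <- vector("list", nrow(contacts))
      for (r in seq_len(nrow(contacts))) {
        ra <- prot[prot$chain == contacts$chain[r] &
                     prot$resno == contacts$resno[r], , drop = FALSE]
        rxyz <- apply_rigid(as.matrix(ra[, c("x", "y", "z")]),
                            fit$rotation, fit$translation)
        ra$x <- rxyz[, 1]; ra$y <- rxyz[, 2]; ra$z <- rxyz[, 3]
        res_list[[r]] <- ra
      }
      envs[[length(envs) + 1L]] <- list(
        run_id = traj$run_id, time = snap$time, probe_id = pr$probe_id[1L],
        probe = pr_t, residues = contacts, residue_atoms = res_list,
        rmsd = fit$rmsd)
    }
  }
  structure(envs, class = "residue_environment_set",
            n_checked = n_checked, n_skipped = n_skipped)
}

#' Concatenate residue environment sets
#'
#' @param ... `residue_environment_set` objects (or a single list of them).
#' @return One combined `residue_environment_set`.
#' @export
combine_environments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "residue_environment_set"))
    sets <- sets[[1L]]
  out <- do.call(c, lapply(sets, unclass))
  structure(out %||% list(), class = "residue_environment_set",
            n_checked = sum(vapply(sets, function(s) attr(s, "n_checked") %||% 0L,
                                   numeric(1))),
            n_skipped = sum(vapply(sets, function(s) attr(s, "n_skipped") %||% 0L,
                                   numeric(1))))
}

#' @export
print.residue_environment_set <- function(x, ...) {
  cat(sprintf("residue_environment_set: %d environments (%d poses checked, %d skipped)\n",
              length(x), attr(x, "n_checked") %||% NA,
              attr(x, "n_skipped") %||% NA))
  invisible(x)
}
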