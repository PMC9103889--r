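# Data model for protein + probe trajectories: snapshots hold one flat atom
# table (protein and probe copies together), trajectories hold a time-ordered
# list of snapshots with a constant time step.

ATOM_COLS <- c("record", "name", "resname", "chain", "resno",
               "x", "y", "z", "element", "heavy", "is_probe", "probe_id")

#' Build an atom table
#'
#' The flat per-atom data frame used throughout the package.  `heavy` is
#' derived from the element (everything but H/D), `probe_id` identifies the
#' probe copy an atom belongs to (`NA` for protein atoms).
#'
#' @param name,resname,chain,resno,element Per-atom PDB fields.
#' @param coords `n x 3` matrix of coordinates in Angstrom.
#' @param record `"ATOM"` or `"HETATM"` per atom (recycled).
#' @param is_probe Logical per atom (recycled).
#' @param probe_id Probe copy identifier per atom (`NA` for protein).
#' @return A data frame with the canonical atom columns.
#' @keywords internal
#' @export
atom_table <- function(name, resname, chain, resno, coords, element,
                       record = "ATOM", is_probe = FALSE, probe_id = NA_character_) {
  coords <- as_points(coords)
  n <- nrow(coords)
  df <- data.frame(
    record = rep_len(as.character(record), n),
    name = as.character(name),
    resname = as.character(resname),
    chain = rep_len(as.character(chain), n),
    resno = rep_len(as.integer(resno), n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    element = toupper(as.character(element)),
    stringsAsFactors = FALSE
  )
  df$heavy <- !(df$element %in% c("H", "D"))
  df$is_probe <- rep_len(as.logical(is_probe), n)
  df$probe_id <- rep_len(as.character(probe_id), n)
  df
}

#' Create a snapshot
#'
#' @param time Snapshot time in ps (non-negative).
#' @param atoms Atom table (see [atom_table()]).
#' @param box Orthorhombic box lengths in Angstrom, or `NULL` if unknown.
#' @return An object of class `snapshot`.
#' @export
snapshot <- function(time, atoms, box = NULL) {
  check_scalar_number(time, "time")
  if (time < 0) stop_data("snapshot time must be non-negative (got %g)", time)
  if (!is.data.frame(atoms) || !all(ATOM_COLS %in% names(atoms)))
    stop_data("'atoms' must be an atom table with columns: %s",
              paste(ATOM_COLS, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_data("snapshot atoms contain non-finite coordinates")
  ids <- unique(atoms$probe_id[atoms$is_probe])
  if (anyNA(ids)) stop_data("probe atoms must carry a probe_id")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop_data("'box' must be 3 positive lengths")
  }
  structure(list(time = as.numeric(time), atoms = atoms, box = box),
            class = "snapshot")
}

#' Protein atoms of a snapshot
#'
#' @param snap A [snapshot()].
#' @param heavy_only Keep heavy atoms only (default FALSE).
#' @return Atom table subset.
#' @export
protein_atoms <- function(snap, heavy_only = FALSE) {
  a <- snap$atoms[!snap$atoms$is_probe, , drop = FALSE]
  if (heavy_only) a <- a[a$heavy, , drop = FALSE]
  a
}

#' Probe copies of a snapshot
#'
#' @param snap A [snapshot()].
#' @param id Optional probe copy id; when given, that copy's atom table is
#'   returned, otherwise a named list of atom tables, one per copy.
#' @param heavy_only Keep heavy atoms only (default FALSE).
#' @return Atom table or named list of atom tables.
#' @export
probe_atoms <- function(snap, id = NULL, heavy_only = FALSE) {
  a <- snap$atoms[snap$atoms$is_probe, , drop = FALSE]
  if (heavy_only) a <- a[a$heavy, , drop = FALSE]
  if (!is.null(id)) {
    out <- a[a$probe_id == id, , drop = FALSE]
    if (nrow(out) == 0L) stop_data("no probe copy with id '%s'", id)
    return(out)
  }
  split(a, factor(a$probe_id, levels = unique(a$probe_id)))
}

coords_of <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(m) <- atoms$name
  m
}

#' Create a trajectory
#'
#' @param run_id Identifier of the independent run this trajectory came from.
#' @param snapshots List of [snapshot()]s with strictly increasing, evenly
#'   spaced times.
#' @param timestep Time step in ps; inferred from the snapshot times when
#'   omitted.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(run_id, snapshots, timestep = NULL) {
  if (!is.list(snapshots) || length(snapshots) < 1L)
    stop_data("'snapshots' must be a non-empty list")
  if (!all(vapply(snapshots, inherits, logical(1), "snapshot")))
    stop_data("'snapshots' must all be snapshot objects")
  times <- vapply(snapshots, `[[`, numeric(1), "time")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop_data("snapshot times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * max(dt))
      stop_data("snapshot times must be evenly spaced (got steps %g..%g ps)",
                min(dt), max(dt))
    inferred <- dt[1L]
  } else inferred <- NA_real_
  if (is.null(timestep)) timestep <- inferred
  else if (!is.na(inferred) && abs(timestep - inferred) > 1e-6)
    stop_data("declared timestep %g ps disagrees with snapshot spacing %g ps",
              timestep, inferred)
  structure(list(run_id = run_id, snapshots = snapshots,
                 timestep = as.numeric(timestep), times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  s1 <- x$snapshots[[1L]]
  cat(sprintf("trajectory '%s': %d snapshots, timestep %g ps, %d atoms (%d probe copies)\n",
              as.character(x$run_id), length(x$snapshots), x$timestep,
              nrow(s1$atoms), length(unique(s1$atoms$probe_id[s1$atoms$is_probe]))))
  invisible(x)
}

#' Snapshot schedule of a production window
#'
#' Returns the times `t_start + k * interval` for
#' `k = 1 .. floor((t_end - t_start) / interval)`, i.e. the half-open
#' convention `(t_start, t_end]`.  With a 20-40 ns window sampled every
#' 10 ps this yields exactly 2000 snapshot times.
#'
#' @param t_start,t_end Window bounds in ps, `t_end >= t_start`.
#' @param interval Sampling interval in ps (> 0).
#' @return Numeric vector of snapshot times (possibly empty).
#' @examples
#' length(snapshot_schedule(20000, 40000, 10))  # 2000
#' @export
snapshot_schedule <- function(t_start, t_end, interval) {
  check_scalar_number(t_start, "t_start")
  check_scalar_number(t_end, "t_end")
  check_scalar_number(interval, "interval", positive = TRUE)
  if (t_end < t_start) stop_config("'t_end' must be >= 't_start'")
  n <- floor((t_end - t_start) / interval + 1e-9)
  if (n < 1) return(numeric(0))
  t_start + seq_len(n) * interval
}

#' Number of probe molecules at a target concentration
#'
#' `round(molarity * N_A * volume * 1e-27)` with
#' `N_A = 6.02214076e23 / mol`; volume in cubic Angstrom, concentration in
#' mol/L.  At 0.25 M a box of 1e6 cubic Angstrom holds 151 probes.
#'
#' @param box_volume Box volume in cubic Angstrom (> 0).
#' @param molarity Probe concentration in mol/L (> 0).
#' @return Integer number of probe copies.
#' @export
probe_count_for_concentration <- function(box_volume, molarity) {
  check_scalar_number(box_volume, "box_volume", positive = TRUE)
  check_scalar_number(molarity, "molarity", positive = TRUE)
  as.integer(round(molarity * 6.02214076e23 * box_volume * 1e-27))
}

# ---------------------------------------------------------------------------
# Rigid-body superposition

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation `R` and translation `t` minimising the RMSD
#' of `R %*% x + t` against `target` over paired points.  Reflections are
#' never returned; if the best orthogonal fit would require one, the best
#' proper rotation is used and the (larger) RMSD reported honestly.
#'
#' @param mobile,target Paired `n x 3` coordinate matrices, `n >= 3`.
#' @return A list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
kabsch <- function(mobile, target) {
  mobile <- as_points(mobile, allow_empty = FALSE, what = "mobile")
  target <- as_points(target, allow_empty = FALSE, what = "target")
  if (nrow(mobile) != nrow(target))
    stop_data("'mobile' and 'target' must have the same number of points")
  if (nrow(mobile) < 3L)
    stop_data("underdetermined fit: need at least 3 paired points")
  mu_m <- colMeans(mobile)
  mu_t <- colMeans(target)
  P <- sweep(mobile, 2L, mu_m)
  Q <- sweep(target, 2L, mu_t)
  # degenerate (collinear) configurations cannot pin down the rotation
  sv_p <- svd(P)$d
  if (sv_p[2L] < 1e-8 * max(sv_p[1L], 1))
    stop_data("underdetermined fit: points are collinear or coincident")
  C <- crossprod(P, Q)            # 3x3 covariance
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(mu_t - R %*% mu_m)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords `n x 3` matrix.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 translation vector.
#' @return Transformed `n x 3` matrix.
#' @export
apply_rigid <- function(coords, rotation, translation = c(0, 0, 0)) {
  coords <- as_points(coords)
  sweep(coords %*% t(rotation), 2L, as.numeric(translation), "+")
}

transform_snapshot <- function(snap, rotation, translation) {
  xyz <- apply_rigid(as.matrix(snap$atoms[, c("x", "y", "z")]),
                     rotation, translation)
  snap$atoms$x <- xyz[, 1]; snap$atoms$y <- xyz[, 2]; snap$atoms$z <- xyz[, 3]
  snap
}

# Deterministic principal-axes frame of a point cloud: centroid to the
# origin, covariance eigenvectors as axes, axis signs fixed by the sign of
# the third central moment (falling back to the largest-|coordinate| sign),
# handedness forced to det = +1.  Makes downstream voxel maps independent of
# the lab-frame orientation of the input.
canonical_frame <- function(coords) {
  coords <- as_points(coords, allow_empty = FALSE)
  mu <- colMeans(coords)
  X <- sweep(coords, 2L, mu)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  A <- ev$vectors                      # columns = axes, decreasing variance
  proj <- X %*% A
  m3 <- colMeans(proj^3)
  for (a in 1:3) {
    s <- if (abs(m3[a]) > 1e-8) sign(m3[a]) else {
      s2 <- sign(proj[which.max(abs(proj[, a])), a]); if (s2 == 0) 1 else s2
    }
    if (s < 0) A[, a] <- -A[, a]
  }
  if (det(A) < 0) A[, 3] <- -A[, 3]    # enforce right-handed frame
  R <- t(A)
  list(rotation = R, translation = as.numeric(-R %*% mu))
}

#' Superpose all snapshots onto a reference protein frame
#'
#' Rigidly fits every snapshot's protein C-alpha atoms onto the reference
#' snapshot (least-squares, Kabsch) and applies the same transform to all
#' atoms including the probes.  Runs fitted to a shared reference end up in
#' one common frame, which is what makes per-run maps combinable.
#'
#' With `canonicalize = TRUE` the reference frame itself is first rotated
#' into the deterministic principal-axes frame of its C-alpha atoms, so the
#' analysis frame (and hence every voxel map) is independent of the global
#' orientation of the input coordinates.
#'
#' @param traj A [trajectory()].
#' @param reference Reference [snapshot()]; defaults to the trajectory's
#'   first snapshot.
#' @param canonicalize Rotate the reference into its principal-axes frame
#'   first (default FALSE).
#' @return The fitted trajectory; per-snapshot C-alpha RMSDs to the
#'   reference are attached as attribute `"rmsd"`.
#' @export
fit_protein_to_reference <- function(traj, reference = NULL,
                                     canonicalize = FALSE) {
  if (!inherits(traj, "trajectory")) stop_data("'traj' must be a trajectory")
  if (is.null(reference)) reference <- traj$snapshots[[1L]]
  if (!inherits(reference, "snapshot"))
    stop_data("'reference' must be a snapshot")
  ref_prot <- protein_atoms(reference)
  ref_ca <- ref_prot[ref_prot$name == "CA", , drop = FALSE]
  if (nrow(ref_ca) < 3L)
    stop_data("underdetermined fit: reference has %d C-alpha atoms (need >= 3)",
              nrow(ref_ca))
  ref_xyz <- as.matrix(ref_ca[, c("x", "y", "z")])
  if (canonicalize) {
    cf <- canonical_frame(ref_xyz)
    ref_xyz <- apply_rigid(ref_xyz, cf$rotation, cf$translation)
  }
  n_atoms <- nrow(traj$snapshots[[1L]]$atoms)
  rmsds <- numeric(length(traj$snapshots))
  for (m in seq_along(traj$snapshots)) {
    snap <- traj$snapshots[[m]]
    if (nrow(snap$atoms) != n_atoms)
      stop_data("snapshot %d has %d atoms, expected %d", m,
                nrow(snap$atoms), n_atoms)
    prot <- protein_atoms(snap)
    ca <- prot[prot$name == "CA", , drop = FALSE]
    if (nrow(ca) != nrow(ref_ca))
      stop_data("snapshot %d has %d C-alpha atoms, reference has %d",
                m, nrow(ca), nrow(ref_ca))
    fit <- kabsch(as.matrix(ca[, c("x", "y", "z")]), ref_xyz)
    traj$snapshots[[m]] <- transform_snapshot(snap, fit$rotation,
                                              fit$translation)
    rmsds[m] <- fit$rmsd
  }
  attr(traj, "rmsd") <- rmsds
  traj
}
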