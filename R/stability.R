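# Stability filter: a probe pose is "stable" when the molecule moved less
# than 3 A (strict) from where it was 500 ps earlier.  Displacements use the
# probe heavy-atom centroid (configurable to a named anchor atom) with a
# minimum-image correction so a periodic wrap is not mistaken for a jump.

probe_position_series <- function(traj, probe_id, anchor = NULL) {
  t(vapply(traj$snapshots, function(s) {
    pr <- probe_atoms(s, id = probe_id, heavy_only = TRUE)
    if (!is.null(anchor)) {
      sel <- pr[pr$name == anchor, , drop = FALSE]
      if (nrow(sel) == 0L)
        stop_data("probe '%s' has no atom named '%s'", probe_id, anchor)
      c(sel$x[1L], sel$y[1L], sel$z[1L])
    } else {
      c(mean(pr$x), mean(pr$y), mean(pr$z))
    }
  }, numeric(3L)))
}

min_image_delta <- function(delta, box) {
  if (is.null(box)) return(delta)
  delta - sweep(round(sweep(delta, 2L, box, "/")), 2L, box, "*")
}

#' Displacement of one probe over a time lag
#'
#' Displacement at time `t` is the Euclidean distance between the probe's
#' position at `t` and at `t - lag` (minimum-image under the orthorhombic
#' box); it is undefined for the first `lag` of the trajectory.
#'
#' @param traj A [trajectory()].
#' @param probe_id Probe copy id.
#' @param lag Time lag in ps (default 500); must be an integer multiple of
#'   the trajectory time step.
#' @param anchor Optional probe atom name to track instead of the heavy-atom
#'   centroid.
#' @return Data frame with `time` and `displacement` for the defined frames.
#' @export
displacement_series <- function(traj, probe_id, lag = 500, anchor = NULL) {
  if (!inherits(traj, "trajectory")) stop_data("'traj' must be a trajectory")
  check_scalar_number(lag, "lag", positive = TRUE)
  nlag <- lag / traj$timestep
  if (abs(nlag - round(nlag)) > 1e-6)
    stop_config("lag (%g ps) must be an integer multiple of the time step (%g ps)",
                lag, traj$timestep)
  nlag <- as.integer(round(nlag))
  pos <- probe_position_series(traj, probe_id, anchor)
  n <- nrow(pos)
  if (n <= nlag)
    return(data.frame(time = numeric(0), displacement = numeric(0)))
  box <- traj$snapshots[[1L]]$box
  delta <- pos[(nlag + 1L):n, , drop = FALSE] - pos[1L:(n - nlag), , drop = FALSE]
  delta <- min_image_delta(delta, box)
  data.frame(time = traj$times[(nlag + 1L):n],
             displacement = sqrt(rowSums(delta^2)))
}

#' Stability verdicts for all probe copies of a run
#'
#' A pose is stable iff its displacement over the lag is strictly below the
#' cutoff (`< 3` Angstrom by default; a displacement of exactly 3.0 is
#' unstable).  No verdict exists for the first `lag` window of the run.
#'
#' @inheritParams displacement_series
#' @param cutoff Displacement cutoff in Angstrom (default 3, strict).
#' @return Data frame with `run_id`, `probe_id`, `time`, `displacement`,
#'   `stable`.
#' @export
stable_mask <- function(traj, lag = 500, cutoff = 3, anchor = NULL) {
  check_scalar_number(cutoff, "cutoff", positive = TRUE)
  ids <- unique(traj$snapshots[[1L]]$atoms$probe_id[
    traj$snapshots[[1L]]$atoms$is_probe])
  out <- lapply(ids, function(id) {
    d <- displacement_series(traj, id, lag = lag, anchor = anchor)
    if (nrow(d) == 0L) return(NULL)
    data.frame(run_id = as.character(traj$run_id), probe_id = id,
               time = d$time, displacement = d$displacement,
               stable = d$displacement < cutoff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out %||% data.frame(run_id = character(0), probe_id = character(0),
                      time = numeric(0), displacement = numeric(0),
                      stable = logical(0))
}

#' Filter residue environments by probe stability
#'
#' Keeps only environments whose probe pose has a stable verdict at that
#' time.  Environments in the initial window with no verdict are dropped
#' and counted separately; the removed fraction is computed over the
#' environments that had a verdict.
#'
#' @param environments A [extract_environments()] result (possibly combined
#'   across runs).
#' @param verdicts Row-bound [stable_mask()] output covering the runs.
#' @return List with `environments` (the kept subset), `removed_fraction`,
#'   `n_input`, `n_kept`, `n_undefined` (no-verdict drops).
#' @export
filter_environments <- function(environments, verdicts) {
  if (!inherits(environments, "residue_environment_set"))
    stop_data("'environments' must be a residue_environment_set")
  need <- c("run_id", "probe_id", "time", "stable")
  if (!is.data.frame(verdicts) || !all(need %in% names(verdicts)))
    stop_config("'verdicts' must be a data frame with columns %s",
                paste(need, collapse = ", "))
  vkey <- paste(verdicts$run_id, verdicts$probe_id, verdicts$time, sep = "\r")
  keep <- logical(length(environments))
  n_undefined <- 0L
  for (e in seq_along(environments)) {
    env <- environments[[e]]
    hit <- match(paste(as.character(env$run_id), env$probe_id, env$time,
                       sep = "\r"), vkey)
    if (is.na(hit)) n_undefined <- n_undefined + 1L
    else keep[e] <- verdicts$stable[hit]
  }
  n_with_verdict <- length(environments) - n_undefined
  kept <- structure(unclass(environments)[keep],
                    class = "residue_environment_set",
                    n_checked = attr(environments, "n_checked"),
                    n_skipped = attr(environments, "n_skipped"))
  list(environments = kept,
       removed_fraction = if (n_with_verdict > 0)
         1 - sum(keep) / n_with_verdict else NA_real_,
       n_input = length(environments), n_kept = sum(keep),
       n_undefined = n_undefined)
}
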