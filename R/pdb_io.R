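# Multi-model PDB I/O.  One MODEL/ENDMDL block per snapshot; probe copies
# are identified by residue name and grouped by (chain, residue number).

#' Read a multi-model PDB trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one snapshot.  `ATOM`/`HETATM`
#' records whose residue name equals `probe_resname` are grouped into probe
#' copies keyed by `(chain, residue number)`; everything else is treated as
#' protein.  Hydrogens are kept but flagged non-heavy and excluded from all
#' distance and binning computations downstream.  A `CRYST1` record, when
#' present, supplies the orthorhombic box.
#'
#' @param path PDB file path.
#' @param probe_resname Residue name of the probe molecule (3-letter code).
#' @param run_id Run identifier stored on the trajectory (default: file name).
#' @param timestep Time step between models in ps (default 10).  Model `m`
#'   is assigned time `m * timestep`.
#' @return A [trajectory()].
#' @export
read_multimodel_pdb <- function(path, probe_resname, run_id = NULL,
                                timestep = 10) {
  if (!file.exists(path)) stop_data("PDB file not found: %s", path)
  probe_resname <- toupper(as.character(probe_resname))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(startsWith(rec, "MODEL"))
  model_ends <- which(startsWith(rec, "ENDMDL"))
  if (length(model_starts) == 0L)
    stop_data("format error: no MODEL records in %s", path)
  if (length(model_starts) != length(model_ends))
    stop_data("format error: %d MODEL but %d ENDMDL records in %s",
              length(model_starts), length(model_ends), path)

  box <- NULL
  cry <- which(startsWith(rec, "CRYST1"))
  if (length(cry)) {
    l <- lines[cry[1L]]
    box <- suppressWarnings(as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                         substr(l, 25, 33))))
    if (anyNA(box) || any(box <= 0)) box <- NULL
  }

  parse_block <- function(blk) {
    r <- substr(blk, 1L, 6L)
    at <- blk[startsWith(r, "ATOM") | startsWith(r, "HETATM")]
    if (!length(at)) stop_data("format error: empty MODEL block")
    name <- trimws(substr(at, 13, 16))
    resname <- toupper(trimws(substr(at, 18, 20)))
    chain <- trimws(substr(at, 22, 22))
    resno <- as.integer(trimws(substr(at, 23, 26)))
    x <- as.numeric(substr(at, 31, 38))
    y <- as.numeric(substr(at, 39, 46))
    z <- as.numeric(substr(at, 47, 54))
    element <- toupper(trimws(substr(at, 77, 78)))
    # fall back to the first letter of the atom name when column 77-78 empty
    miss <- !nzchar(element)
    element[miss] <- substr(gsub("[^A-Za-z].*$", "", name[miss]), 1L, 1L)
    if (any(is.na(x) | is.na(y) | is.na(z)))
      stop_data("format error: unparsable coordinates in %s", path)
    is_probe <- resname == probe_resname
    probe_id <- ifelse(is_probe, paste0(chain, ":", resno), NA_character_)
    atom_table(name = name, resname = resname, chain = chain, resno = resno,
               coords = cbind(x, y, z), element = element,
               record = trimws(substr(at, 1, 6)),
               is_probe = is_probe, probe_id = probe_id)
  }

  snaps <- vector("list", length(model_starts))
  n_first <- NULL
  for (m in seq_along(model_starts)) {
    atoms <- parse_block(lines[(model_starts[m] + 1L):(model_ends[m] - 1L)])
    if (is.null(n_first)) n_first <- nrow(atoms)
    else if (nrow(atoms) != n_first)
      stop_data("consistency error: model %d has %d atoms, model 1 has %d",
                m, nrow(atoms), n_first)
    snaps[[m]] <- snapshot(time = m * timestep, atoms = atoms, box = box)
  }
  if (!any(snaps[[1L]]$atoms$is_probe))
    stop_config("configuration error: probe residue name '%s' not present in %s",
                probe_resname, path)
  trajectory(run_id = run_id %||% basename(path), snapshots = snaps,
             timestep = timestep)
}

pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                          x, y, z, element) {
  # atom names shorter than 4 characters start in column 14
  nm <- ifelse(nchar(name) < 4L, paste0(" ", name), name)
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, nm, resname, chain, resno %% 10000L,
          x, y, z, 1, 0, element)
}

#' Write a trajectory as a multi-model PDB
#'
#' Inverse of [read_multimodel_pdb()]: one `MODEL`/`ENDMDL` block per
#' snapshot, a `CRYST1` record when the box is known.  Coordinates are
#' written at PDB precision (0.001 Angstrom).
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (!inherits(traj, "trajectory")) stop_data("'traj' must be a trajectory")
  con <- file(path, "w")
  on.exit(close(con))
  box <- traj$snapshots[[1L]]$box
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1], box[2], box[3], 90, 90, 90), con)
  for (m in seq_along(traj$snapshots)) {
    a <- traj$snapshots[[m]]$atoms
    writeLines(sprintf("MODEL %8d", m), con)
    writeLines(pdb_atom_line(a$record, seq_len(nrow(a)), a$name, a$resname,
                             a$chain, a$resno, a$x, a$y, a$z, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
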