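# Probe definitions: which atoms anchor the superposition and which atom
# relabelings are symmetry-equivalent (e.g. the 12 automorphisms of a
# benzene ring).  Symmetry mappings are supplied explicitly per probe; the
# package ships presets for benzene, catechol and benzamidine.

#' Define a probe molecule
#'
#' @param resname Residue name of the probe (3-letter code).
#' @param alignment_atoms Ordered atom names used for superposition; for
#'   fully symmetric rigid probes this is typically all heavy atoms (all
#'   carbons for benzamidine).
#' @param symmetry_mappings List of permutations of `alignment_atoms`; each
#'   mapping says "the atom named `mapping[i]` may play the role of reference
#'   atom `alignment_atoms[i]`".  Must contain at least the identity.
#' @param coords Optional reference coordinates: an `n x 3` matrix with atom
#'   names as row names.  Required when the probe serves as the reference
#'   frame of an interaction profile.
#' @param elements Optional element symbols parallel to `rownames(coords)`.
#' @return An object of class `probe_definition`.
#' @export
probe_definition <- function(resname, alignment_atoms,
                             symmetry_mappings = list(alignment_atoms),
                             coords = NULL, elements = NULL) {
  resname <- toupper(as.character(resname))
  alignment_atoms <- as.character(alignment_atoms)
  if (length(alignment_atoms) < 3L)
    stop_config("need at least 3 alignment atoms (got %d)",
                length(alignment_atoms))
  if (anyDuplicated(alignment_atoms))
    stop_config("alignment atom names must be unique")
  if (!is.list(symmetry_mappings) || length(symmetry_mappings) < 1L)
    stop_config("'symmetry_mappings' must be a non-empty list")
  for (m in symmetry_mappings) {
    if (!setequal(m, alignment_atoms) || length(m) != length(alignment_atoms))
      stop_config("symmetry mapping (%s) is not a permutation of the alignment atoms",
                  paste(m, collapse = ", "))
  }
  if (!any(vapply(symmetry_mappings, identical, logical(1), alignment_atoms)))
    symmetry_mappings <- c(list(alignment_atoms), symmetry_mappings)
  if (!is.null(coords)) {
    coords <- as_points(coords, allow_empty = FALSE, what = "coords")
    if (is.null(rownames(coords)))
      stop_config("'coords' must have atom names as row names")
    missing <- setdiff(alignment_atoms, rownames(coords))
    if (length(missing))
      stop_config("alignment atoms absent from coords: %s",
                  paste(missing, collapse = ", "))
    if (is.null(elements))
      elements <- substr(gsub("[^A-Za-z].*$", "", rownames(coords)), 1L, 1L)
  }
  structure(
    list(resname = resname, alignment_atoms = alignment_atoms,
         symmetry_mappings = lapply(symmetry_mappings, as.character),
         coords = coords, elements = if (is.null(coords)) NULL else toupper(elements)),
    class = "probe_definition"
  )
}

#' @export
print.probe_definition <- function(x, ...) {
  cat(sprintf("probe '%s': %d alignment atoms (%s), %d symmetry mapping(s)%s\n",
              x$resname, length(x$alignment_atoms),
              paste(x$alignment_atoms, collapse = " "),
              length(x$symmetry_mappings),
              if (is.null(x$coords)) "" else ", reference coordinates set"))
  invisible(x)
}

#' Built-in three-atom toy probe
#'
#' A rigid planar three-heavy-atom probe (a carboxylate-like C + two
#' equivalent O fragment) used by the synthetic trajectory generator.  Its
#' C2 symmetry axis is the x axis of the reference frame; the two oxygens
#' are symmetry-equivalent, so the template carries two symmetry mappings
#' and exercises the symmetry-aware superposition by default.
#'
#' @return A [probe_definition()] with reference coordinates (`C1` at the
#'   origin).
#' @export
toy_probe_template <- function() {
  coords <- rbind(
    C1 = c(0, 0, 0),
    O1 = c(1.25 * cospi(65 / 180), 1.25 * sinpi(65 / 180), 0),
    O2 = c(1.25 * cospi(65 / 180), -1.25 * sinpi(65 / 180), 0)
  )
  probe_definition(
    resname = "PRB",
    alignment_atoms = c("C1", "O1", "O2"),
    symmetry_mappings = list(c("C1", "O1", "O2"), c("C1", "O2", "O1")),
    coords = coords,
    elements = c("C", "O", "O")
  )
}

#' Shipped probe presets
#'
#' Alignment-atom and symmetry-mapping presets for the three reference
#' probes: benzamidine (aligned on all carbon atoms), catechol and benzene
#' (aligned on all heavy atoms).  Benzene additionally ships idealized ring
#' coordinates.
#'
#' @param name One of `"benzene"`, `"catechol"`, `"benzamidine"`, or `NULL`
#'   to list available presets.
#' @return A [probe_definition()], or a character vector of preset names.
#' @export
probe_preset <- function(name = NULL) {
  path <- system.file("extdata", "probe_presets.yaml", package = "probemap")
  presets <- yaml::read_yaml(path)
  if (is.null(name)) return(names(presets))
  name <- tolower(name)
  if (!name %in% names(presets))
    stop_config("unknown probe preset '%s' (available: %s)", name,
                paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  coords <- NULL
  elements <- NULL
  if (!is.null(p$coords)) {
    coords <- do.call(rbind, lapply(p$coords, function(a) as.numeric(a$xyz)))
    rownames(coords) <- vapply(p$coords, `[[`, character(1), "name")
    elements <- vapply(p$coords, `[[`, character(1), "element")
  }
  probe_definition(resname = p$resname,
                   alignment_atoms = as.character(p$alignment_atoms),
                   symmetry_mappings = lapply(p$symmetry_mappings, as.character),
                   coords = coords, elements = elements)
}
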