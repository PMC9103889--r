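# Residue typing: the five-class scheme (acidic / basic / hydrophilic /
# hydrophobic / aromatic) with glycine excluded because it has no C-beta.

RESIDUE_TYPES <- c("acidic", "basic", "hydrophilic", "hydrophobic", "aromatic")

#' Residue type scheme
#'
#' Loads the residue classification used for interaction profiles: Asp/Glu
#' acidic; Arg/His/Lys basic (His counts as basic regardless of protonation
#' state in the input); Asn/Cys/Gln/Ser/Thr hydrophilic; Ala/Ile/Leu/Met/
#' Pro/Val hydrophobic; Phe/Trp/Tyr aromatic; Gly excluded (no C-beta).
#' The scheme is a packaged TSV so users can supply their own.
#'
#' @param path Optional TSV with columns `resname` and `type`; defaults to
#'   the packaged scheme.
#' @return A named character vector mapping 3-letter residue codes to types
#'   (`"excluded"` marks residues outside the scheme), with class
#'   `residue_type_scheme`.
#' @export
residue_type_scheme <- function(path = NULL) {
  path <- path %||% system.file("extdata", "residue_types.tsv",
                                package = "probemap")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("resname", "type") %in% names(tab)))
    stop_config("scheme file must have columns 'resname' and 'type'")
  bad <- setdiff(unique(tab$type), c(RESIDUE_TYPES, "excluded"))
  if (length(bad))
    stop_config("unknown residue type(s) in scheme: %s",
                paste(bad, collapse = ", "))
  scheme <- stats::setNames(tab$type, toupper(tab$resname))
  class(scheme) <- "residue_type_scheme"
  scheme
}

#' Classify residues by type
#'
#' @param resname Character vector of 3-letter residue codes.
#' @param scheme A [residue_type_scheme()].
#' @param on_unknown `"error"` (default) raises an unknown-residue error for
#'   codes outside the scheme; `"exclude"` classifies them as `"excluded"`
#'   with a warning (useful for modified residues).
#' @return Character vector of types (`"acidic"`, ..., `"aromatic"` or
#'   `"excluded"`).
#' @examples
#' classify_residue(c("ASP", "GLY"))
#' @export
classify_residue <- function(resname, scheme = residue_type_scheme(),
                             on_unknown = c("error", "exclude")) {
  on_unknown <- match.arg(on_unknown)
  resname <- toupper(as.character(resname))
  out <- unclass(scheme)[resname]
  unknown <- is.na(out)
  if (any(unknown)) {
    codes <- unique(resname[unknown])
    if (on_unknown == "error")
      stop_data("unknown residue code(s): %s", paste(codes, collapse = ", "))
    warnf("excluding unknown residue code(s): %s", paste(codes, collapse = ", "))
    out[unknown] <- "excluded"
  }
  unname(out)
}

#' Packaged reference protein list
#'
#' The 15-entry PDB code / chain list of diverse proteins used for
#' residue-environment sampling, shipped as a data fixture.
#'
#' @return A data frame with columns `pdb_code`, `chain`, `protein_name`.
#' @export
table1_proteins <- function() {
  path <- system.file("extdata", "table1_proteins.tsv", package = "probemap")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
}
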