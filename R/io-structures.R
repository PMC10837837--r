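# PDB I/O. Parsing is delegated to bio3d; this layer resolves alternate
# locations, drops heteroatoms and waters, and produces the atom tibble used
# by the structure-feature functions.

#' Read a protein structure from a PDB file
#'
#' Reads the first model and first chain (with a warning if more are present),
#' excludes HETATM records and waters, and resolves alternate locations by
#' highest occupancy then first occurrence.
#'
#' @param path Path to a PDB coordinate file.
#' @return An atom tibble with columns `residue_index`, `residue_type`
#'   (3-letter code), `atom_name`, `element`, `x`, `y`, `z` (Angstrom).
#'   Residues missing all of N/CA/C are flagged in the
#'   `incomplete_backbone` attribute.
#' @export
read_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("zero residues after filtering: ", path))
  chains <- unique(at$chain)
  if (length(chains) > 1) {
    warn(paste0("multiple chains in ", path, "; using chain ", chains[1]))
    at <- at[at$chain == chains[1], , drop = FALSE]
  }
  # alternate locations: keep highest occupancy, then first-seen
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, at$elety)
  ord <- order(key, -occ, seq_len(nrow(at)))
  first <- !duplicated(key[ord])
  keep <- logical(nrow(at))
  keep[ord[first]] <- TRUE
  at <- at[keep, , drop = FALSE]
  at <- at[order(at$resno, at$eleno), , drop = FALSE]

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  }
  atoms <- tibble::tibble(
    residue_index = at$resno,
    residue_type = at$resid,
    atom_name = at$elety,
    element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z
  )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) abort("non-finite coordinates")
  bb <- atoms |>
    dplyr::group_by(.data$residue_index) |>
    dplyr::summarise(has_bb = any(.data$atom_name %in% c("N", "CA", "C")))
  incomplete <- bb$residue_index[!bb$has_bb]
  if (length(incomplete) > 0) {
    inform(paste0(length(incomplete), " residue(s) missing all backbone atoms"))
  }
  attr(atoms, "incomplete_backbone") <- incomplete
  atoms
}

#' @rdname read_pdb
#' @param atoms Atom tibble to write.
#' @export
write_pdb <- function(atoms, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$residue_index,
    resid = atoms$residue_type,
    elety = atoms$atom_name,
    chain = "A",
    elesy = atoms$element
  )
  invisible(path)
}
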