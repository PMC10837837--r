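# Solvent-accessible surface area by Shrake-Rupley point sampling, relative
# accessibility against extended Gly-X-Gly references, and the core/surface
# partition.

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius `probe` over every atom: quasi-uniform points are
#' placed on each atom's expanded sphere (radius `r_atom + probe`) and a point
#' is buried if it lies strictly inside any other atom's expanded sphere (a
#' point exactly on another sphere counts as exposed). The atom SASA is
#' `4*pi*(r+probe)^2` times the exposed fraction. Hydrogens are ignored;
#' an element without a shipped van der Waals radius is an error.
#'
#' @param atoms Atom tibble (see [read_pdb()]).
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere points per atom.
#' @param radii Radius table (`element`, `radius`); defaults to the shipped set
#'   (C 1.70, N 1.55, O 1.52, S 1.80).
#' @return The input (hydrogens dropped) with a `sasa` column (Angstrom^2).
#' @export
#' @examples
#' atoms <- tibble::tibble(residue_index = 1, residue_type = "ALA",
#'                         atom_name = "CB", element = "C", x = 0, y = 0, z = 0)
#' compute_sasa(atoms)$sasa  # 4*pi*(1.7+1.4)^2
compute_sasa <- function(atoms, probe = 1.4, n_points = 960, radii = vdw_radii()) {
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  lut <- setNames(radii$radius, radii$element)
  unknown <- setdiff(unique(atoms$element), names(lut))
  if (length(unknown) > 0) {
    abort(paste0("unknown element(s) without van der Waals radius: ",
                 paste(unknown, collapse = ", ")))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r_exp <- unname(lut[atoms$element]) + probe
  n_atoms <- nrow(atoms)
  pts <- sphere_points(n_points)
  sasa <- numeric(n_atoms)
  d2 <- as.matrix(dist(xyz))^2
  for (i in seq_len(n_atoms)) {
    nb <- which(d2[i, ] < (r_exp[i] + r_exp)^2 & seq_len(n_atoms) != i)
    p <- sweep(pts * r_exp[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & (dd >= r_exp[j]^2)
      if (!any(exposed)) break
    }
    sasa[i] <- 4 * pi * r_exp[i]^2 * mean(exposed)
  }
  dplyr::mutate(atoms, sasa = sasa)
}

#' Per-residue SASA
#'
#' Sums atom SASA (from [compute_sasa()]) per residue.
#'
#' @param atoms_sasa Atom tibble with a `sasa` column.
#' @return Tibble with `residue_index`, `residue_type`, `sasa`.
#' @export
residue_sasa <- function(atoms_sasa) {
  atoms_sasa |>
    dplyr::group_by(.data$residue_index, .data$residue_type) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop")
}

#' Maximum accessible surface per residue type
#'
#' Reference SASA of residue X as the central residue of an extended
#' (phi = psi = 180 degrees) Gly-X-Gly tripeptide, computed with the same
#' engine and settings as [compute_sasa()]. Values are computed once per
#' session and cached.
#'
#' @inheritParams compute_sasa
#' @return Named numeric vector (3-letter residue type -> Angstrom^2).
#' @export
max_asa_table <- function(probe = 1.4, n_points = 960) {
  key <- sprintf("maxasa_%g_%d", probe, n_points)
  if (!is.null(the[[key]])) return(the[[key]])
  vals <- vapply(unname(AA_THREE), function(res) {
    pep <- build_peptide(c("GLY", res, "GLY"), "extended")
    rs <- residue_sasa(compute_sasa(pep, probe = probe, n_points = n_points))
    rs$sasa[rs$residue_index == 2]
  }, numeric(1))
  the[[key]] <- vals
  vals
}

#' Relative solvent accessibility and core/surface partition
#'
#' RSA is residue SASA divided by the residue type's maximum accessible
#' surface ([max_asa_table()]). A residue is `core` when RSA <= `core_rsa`
#' (boundary inclusive) and `surface` otherwise. RSA may slightly exceed 1
#' for termini.
#'
#' @param residues Tibble with `residue_index`, `residue_type`, `sasa`
#'   (from [residue_sasa()]).
#' @param core_rsa Core threshold on RSA.
#' @param max_asa Reference table; defaults to the engine-derived one.
#' @return The input with `rsa` and `region` appended.
#' @export
relative_accessibility <- function(residues, core_rsa = 0.20, max_asa = max_asa_table()) {
  unknown <- setdiff(unique(residues$residue_type), names(max_asa))
  if (length(unknown) > 0) {
    abort(paste0("residue type(s) absent from max ASA table: ",
                 paste(unknown, collapse = ", ")))
  }
  residues |>
    dplyr::mutate(
      rsa = .data$sasa / unname(max_asa[.data$residue_type]),
      # tiny tolerance so an RSA equal to the threshold up to floating-point
      # noise classifies as core (the boundary is inclusive)
      region = ifelse(.data$rsa <= core_rsa + 1e-9, "core", "surface")
    )
}
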