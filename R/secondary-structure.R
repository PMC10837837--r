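# Torsion-window secondary-structure assignment: three classes (H helix,
# E sheet, C loop) from backbone phi/psi, with minimum run lengths and chain
# breaks splitting runs.

#' Assign secondary structure from backbone torsions
#'
#' A residue is a helix candidate if phi is within `[-100, -30]` and psi
#' within `[-80, -5]` degrees, and a strand candidate if phi is within
#' `[-180, -90]` and psi within `[90, 180]` or `[-180, -170]`. Runs of at
#' least `min_helix` consecutive helix candidates are assigned `H`, runs of at
#' least `min_strand` strand candidates `E`, everything else (including chain
#' termini lacking a full torsion) `C`. A CA-CA distance above `break_dist`
#' splits runs.
#'
#' @param atoms Atom tibble with backbone N, CA, C per residue.
#' @param min_helix,min_strand Minimum run lengths.
#' @param break_dist Chain-break CA-CA distance (Angstrom).
#' @return Tibble with `residue_index`, `residue_type`, `phi`, `psi`, `ss`
#'   (`H`/`E`/`C`).
#' @export
assign_secondary_structure <- function(atoms, min_helix = 4, min_strand = 3,
                                       break_dist = 4.5) {
  res_idx <- sort(unique(atoms$residue_index))
  n <- length(res_idx)
  getc <- function(i, name) atom_coords(atoms, res_idx[i], name)
  res_type <- vapply(res_idx, function(ri) {
    atoms$residue_type[atoms$residue_index == ri][1]
  }, character(1))

  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  broken_before <- rep(FALSE, n)  # chain break between i-1 and i
  for (i in seq_len(n)) {
    Ni <- getc(i, "N"); CAi <- getc(i, "CA"); Ci <- getc(i, "C")
    if (i > 1) {
      CAp <- getc(i - 1, "CA")
      if (is.null(CAp) || is.null(CAi) || vnorm(CAi - CAp) > break_dist ||
          res_idx[i] - res_idx[i - 1] != 1) {
        broken_before[i] <- TRUE
      }
    }
    if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci)) {
      if (i > 1 && !broken_before[i]) {
        Cp <- getc(i - 1, "C")
        if (!is.null(Cp)) phi[i] <- dihedral(Cp, Ni, CAi, Ci)
      }
      if (i < n && !broken_before[i + 1]) {
        Nn <- getc(i + 1, "N")
        if (!is.null(Nn)) psi[i] <- dihedral(Ni, CAi, Ci, Nn)
      }
    }
  }

  helix_cand <- !is.na(phi) & !is.na(psi) &
    phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  strand_cand <- !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -90 & ((psi >= 90 & psi <= 180) | (psi >= -180 & psi <= -170))

  ss <- rep("C", n)
  scan_runs <- function(cand, min_len, label) {
    i <- 1
    while (i <= n) {
      if (cand[i]) {
        j <- i
        while (j + 1 <= n && cand[j + 1] && !broken_before[j + 1]) j <- j + 1
        if (j - i + 1 >= min_len) ss[i:j] <<- label
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    invisible(NULL)
  }
  scan_runs(strand_cand, min_strand, "E")
  scan_runs(helix_cand, min_helix, "H")

  tibble::tibble(residue_index = res_idx, residue_type = res_type,
                 phi = phi, psi = psi, ss = ss)
}
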