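# Deterministic peptide builder: ideal backbone geometry with per-conformation
# phi/psi, plus simplified side chains carrying exactly the functional-group
# atoms the interaction detector consults. Used both as a synthetic-structure
# generator and to build the extended Gly-X-Gly references behind relative
# solvent accessibility.

BOND_N_CA <- 1.46
BOND_CA_C <- 1.52
BOND_C_N <- 1.33
ANGLE_N_CA_C <- 111
ANGLE_CA_C_N <- 117
ANGLE_C_N_CA <- 121

CONFORMATIONS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135),
  extended = c(phi = 180, psi = 180)
)

# simplified side-chain layouts: offsets (along, lateral) from CB in the local
# frame spanned by the CA->CB direction and a perpendicular
side_chain_layout <- function(res) {
  L <- switch(res,
    ALA = NULL,
    GLY = NA,  # no CB at all
    VAL = list(CG1 = c(1.2, 1.0), CG2 = c(1.2, -1.0)),
    LEU = list(CG = c(1.5, 0), CD1 = c(2.7, 1.0), CD2 = c(2.7, -1.0)),
    ILE = list(CG1 = c(1.5, 0.4), CG2 = c(1.0, -1.2), CD1 = c(2.9, 0.6)),
    MET = list(CG = c(1.5, 0), SD = c(3.0, 0), CE = c(4.3, 0)),
    PRO = list(CG = c(1.4, 0.6), CD = c(1.0, 1.8)),
    PHE = ring6_layout(),
    TYR = c(ring6_layout(), list(OH = c(5.69, 0))),
    TRP = list(CG = c(1.5, 0), CD1 = c(2.2, 1.1), CD2 = c(2.5, -0.8),
               NE1 = c(3.5, 0.8), CE2 = c(3.6, -0.5), CE3 = c(2.4, -2.2),
               CZ2 = c(4.7, -1.2), CZ3 = c(3.5, -2.9), CH2 = c(4.6, -2.6)),
    HIS = list(CG = c(1.5, 0), ND1 = c(2.3, 1.1), CD2 = c(2.4, -1.0),
               CE1 = c(3.6, 0.7), NE2 = c(3.7, -0.6)),
    ARG = list(CG = c(1.5, 0), CD = c(2.9, 0), NE = c(4.2, 0), CZ = c(5.5, 0),
               NH1 = c(6.2, 1.1), NH2 = c(6.2, -1.1)),
    LYS = list(CG = c(1.5, 0), CD = c(2.9, 0), CE = c(4.2, 0), NZ = c(5.5, 0)),
    ASP = list(CG = c(1.5, 0), OD1 = c(2.2, 1.1), OD2 = c(2.2, -1.1)),
    GLU = list(CG = c(1.5, 0), CD = c(2.9, 0), OE1 = c(3.6, 1.1), OE2 = c(3.6, -1.1)),
    ASN = list(CG = c(1.5, 0), OD1 = c(2.2, 1.1), ND2 = c(2.2, -1.1)),
    GLN = list(CG = c(1.5, 0), CD = c(2.9, 0), OE1 = c(3.6, 1.1), NE2 = c(3.6, -1.1)),
    SER = list(OG = c(1.4, 0)),
    THR = list(OG1 = c(1.2, 0.9), CG2 = c(1.2, -1.1)),
    CYS = list(SG = c(1.8, 0)),
    abort(paste0("unknown residue type: ", res))
  )
  L
}

# hexagonal aromatic ring in the (along, lateral) plane, CG bonded to CB
ring6_layout <- function() {
  centre <- 1.51 + 1.39
  ang <- c(CG = 180, CD1 = 120, CD2 = 240, CE1 = 60, CE2 = 300, CZ = 0) * pi / 180
  lapply(as.list(ang), function(a) c(centre + 1.39 * cos(a), 1.39 * sin(a)))
}

as_three_letter <- function(sequence) {
  if (length(sequence) == 1 && !sequence[1] %in% names(AA_ONE)) {
    ch <- strsplit(toupper(sequence), "")[[1]]
    bad <- setdiff(ch, names(AA_THREE))
    if (length(bad) > 0) abort(paste0("unknown residue letter(s): ", paste(bad, collapse = ", ")))
    unname(AA_THREE[ch])
  } else {
    bad <- setdiff(toupper(sequence), names(AA_ONE))
    if (length(bad) > 0) abort(paste0("unknown residue type(s): ", paste(bad, collapse = ", ")))
    toupper(sequence)
  }
}

#' Build an idealised peptide structure
#'
#' Constructs backbone coordinates from ideal bond lengths and angles
#' (N-CA 1.46, CA-C 1.52, C-N 1.33 Angstrom; angles 111/117/121 degrees) with
#' phi/psi fixed by the requested conformation (helix -57/-47,
#' strand -139/+135, extended 180/180; omega 180), and places simplified side
#' chains carrying the functional-group atoms used by
#' [detect_interactions()]. Deterministic: identical inputs give identical
#' coordinates.
#'
#' @param sequence Protein sequence, either a one-letter string ("GAG") or a
#'   vector of 3-letter codes (`c("GLY","ALA","GLY")`).
#' @param conformation `"helix"`, `"strand"` or `"extended"`.
#' @return An atom tibble (see [read_pdb()] for columns).
#' @export
#' @examples
#' build_peptide("GAG", "extended")
build_peptide <- function(sequence, conformation = c("extended", "helix", "strand")) {
  conformation <- match.arg(conformation)
  res <- as_three_letter(sequence)
  tors <- CONFORMATIONS[[conformation]]
  n_res <- length(res)

  rows <- vector("list", 0)
  add <- function(i, name, xyz) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      residue_index = i, residue_type = res[i], atom_name = name,
      element = substr(name, 1, 1), x = xyz[1], y = xyz[2], z = xyz[3])
  }

  # backbone
  N <- matrix(NA_real_, n_res, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  a <- (180 - ANGLE_N_CA_C) * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(a), sin(a), 0)
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_N, ANGLE_CA_C_N,
                             tors[["psi"]])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], BOND_N_CA,
                              ANGLE_C_N_CA, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], BOND_CA_C,
                             ANGLE_N_CA_C, tors[["phi"]])
  }
  for (i in seq_len(n_res)) {
    add(i, "N", N[i, ]); add(i, "CA", CA[i, ]); add(i, "C", C[i, ])
    # carbonyl oxygen opposite the next N
    add(i, "O", place_atom(N[i, ], CA[i, ], C[i, ], 1.23, 121,
                           tors[["psi"]] + 180))
    if (res[i] != "GLY") {
      cb <- place_atom(C[i, ], N[i, ], CA[i, ], 1.53, 110.5, -122)
      add(i, "CB", cb)
      layout <- side_chain_layout(res[i])
      if (is.list(layout)) {
        u <- unit(cb - CA[i, ])
        v <- unit(cross3(u, unit(N[i, ] - CA[i, ])))
        for (nm in names(layout)) {
          off <- layout[[nm]]
          add(i, nm, cb + off[1] * u + off[2] * v)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
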