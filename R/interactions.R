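# Residue-residue interaction detection: six classes with configurable
# distance criteria, one contact per residue pair per type (closest
# qualifying distance).

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

CATION_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ", HIS = c("ND1", "NE2"))
ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO", "TYR")
CATION_PI_ATOM <- c(LYS = "NZ", ARG = "CZ")
SULFUR_ATOM <- c(CYS = "SG", MET = "SD")

# numerical tolerance on the inclusive distance boundaries: a pair whose
# defining distance equals a criterion to within floating-point noise counts
# as in contact
EPS_D <- 1e-9

#' Default interaction distance criteria
#'
#' Distance thresholds (Angstrom) of the six interaction classes. All
#' boundaries are inclusive; the aromatic-aromatic class uses a window.
#'
#' @param ... Named overrides, e.g. `ionic = 4.0`.
#' @return Named list of thresholds.
#' @export
interaction_thresholds <- function(...) {
  th <- list(hydrophobic = 5.0, ionic = 6.0, aromatic_min = 4.5,
             aromatic_max = 7.0, aromatic_sulfur = 5.3, cation_pi = 6.0,
             disulfide = 2.2)
  extra <- list(...)
  th[names(extra)] <- extra
  th
}

centroid_of <- function(atoms, residue_index, names_needed) {
  sel <- atoms$residue_index == residue_index & atoms$atom_name %in% names_needed
  if (sum(sel) < length(names_needed)) return(NULL)
  colMeans(as.matrix(atoms[sel, c("x", "y", "z")]))
}

# per-residue interaction groups; NULL where the residue lacks the atoms
residue_groups <- function(atoms) {
  res <- atoms |>
    dplyr::distinct(.data$residue_index, .data$residue_type) |>
    dplyr::arrange(.data$residue_index)
  n_skipped <- 0L
  grab <- function(ri, names_needed) {
    g <- centroid_of(atoms, ri, names_needed)
    if (is.null(g)) n_skipped <<- n_skipped + 1L
    g
  }
  g <- purrr::map2(res$residue_index, res$residue_type, function(ri, rt) {
    out <- list()
    if (rt %in% HYDROPHOBIC_RES) {
      sel <- atoms$residue_index == ri & atoms$element == "C" &
        !(atoms$atom_name %in% c("CA", "C"))
      if (any(sel)) out$carbons <- as.matrix(atoms[sel, c("x", "y", "z")])
    }
    if (rt %in% names(RING_ATOMS)) out$ring <- grab(ri, RING_ATOMS[[rt]])
    if (rt %in% names(CATION_ATOMS)) out$cation <- grab(ri, CATION_ATOMS[[rt]])
    if (rt %in% names(ANION_ATOMS)) out$anion <- grab(ri, ANION_ATOMS[[rt]])
    if (rt %in% names(CATION_PI_ATOM)) out$cpi <- grab(ri, CATION_PI_ATOM[[rt]])
    if (rt %in% names(SULFUR_ATOM)) out$sulfur <- grab(ri, SULFUR_ATOM[[rt]])
    out
  })
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " residue group(s) skipped for missing side-chain atoms"))
  }
  list(index = res$residue_index, type = res$residue_type, groups = g)
}

min_pair_dist <- function(m1, m2) {
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * m1 %*% t(m2)
  sqrt(max(0, min(d2)))
}

#' Detect residue-residue interactions
#'
#' Scans all residue pairs for six interaction classes (inclusive
#' boundaries; `|i - j| >= 2` required for all classes except disulfide):
#' \describe{
#'   \item{hydrophobic}{any side-chain carbon pair of two hydrophobic
#'     residues within 5.0 A}
#'   \item{ionic}{cationic group centroid (Arg NH1/NH2/NE, Lys NZ,
#'     His ND1/NE2) within 6.0 A of an anionic centroid (Asp OD1/OD2,
#'     Glu OE1/OE2)}
#'   \item{aromatic_aromatic}{ring centroids (Phe/Tyr/Trp/His) 4.5-7.0 A apart}
#'   \item{aromatic_sulfur}{Cys SG or Met SD within 5.3 A of a ring centroid}
#'   \item{cation_pi}{Lys NZ or Arg CZ within 6.0 A of a ring centroid}
#'   \item{disulfide}{Cys SG-SG within 2.2 A}
#' }
#' Residues lacking the atoms of a group are skipped with a logged count.
#' One contact is recorded per residue pair per type, at the closest
#' qualifying distance.
#'
#' @param atoms Atom tibble.
#' @param thresholds Criteria from [interaction_thresholds()].
#' @return Tibble with `type`, `res_i`, `res_j` (`res_i < res_j`), `distance`.
#' @export
detect_interactions <- function(atoms, thresholds = interaction_thresholds()) {
  rg <- residue_groups(atoms)
  n <- length(rg$index)
  out <- list()
  emit <- function(type, i, j, d) {
    out[[length(out) + 1]] <<- tibble::tibble(
      type = type, res_i = min(rg$index[i], rg$index[j]),
      res_j = max(rg$index[i], rg$index[j]), distance = d)
  }
  for (i in seq_len(n - 1)) {
    gi <- rg$groups[[i]]
    for (j in (i + 1):n) {
      gj <- rg$groups[[j]]
      sep_ok <- abs(rg$index[j] - rg$index[i]) >= 2
      if (!is.null(gi$sulfur) && !is.null(gj$sulfur) &&
          rg$type[i] == "CYS" && rg$type[j] == "CYS") {
        d <- vnorm(gi$sulfur - gj$sulfur)
        if (d <= thresholds$disulfide + EPS_D) emit("disulfide", i, j, d)
      }
      if (!sep_ok) next
      if (!is.null(gi$carbons) && !is.null(gj$carbons)) {
        d <- min_pair_dist(gi$carbons, gj$carbons)
        if (d <= thresholds$hydrophobic + EPS_D) emit("hydrophobic", i, j, d)
      }
      d_ionic <- c(
        if (!is.null(gi$cation) && !is.null(gj$anion)) vnorm(gi$cation - gj$anion),
        if (!is.null(gi$anion) && !is.null(gj$cation)) vnorm(gi$anion - gj$cation))
      if (length(d_ionic) > 0 && min(d_ionic) <= thresholds$ionic + EPS_D) {
        emit("ionic", i, j, min(d_ionic))
      }
      if (!is.null(gi$ring) && !is.null(gj$ring)) {
        d <- vnorm(gi$ring - gj$ring)
        if (d >= thresholds$aromatic_min - EPS_D && d <= thresholds$aromatic_max + EPS_D) {
          emit("aromatic_aromatic", i, j, d)
        }
      }
      d_as <- c(
        if (!is.null(gi$sulfur) && !is.null(gj$ring)) vnorm(gi$sulfur - gj$ring),
        if (!is.null(gi$ring) && !is.null(gj$sulfur)) vnorm(gi$ring - gj$sulfur))
      if (length(d_as) > 0 && min(d_as) <= thresholds$aromatic_sulfur + EPS_D) {
        emit("aromatic_sulfur", i, j, min(d_as))
      }
      d_cp <- c(
        if (!is.null(gi$cpi) && !is.null(gj$ring)) vnorm(gi$cpi - gj$ring),
        if (!is.null(gi$ring) && !is.null(gj$cpi)) vnorm(gi$ring - gj$cpi))
      if (length(d_cp) > 0 && min(d_cp) <= thresholds$cation_pi + EPS_D) {
        emit("cation_pi", i, j, min(d_cp))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(type = character(), res_i = integer(),
                          res_j = integer(), distance = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$type, .data$res_i, .data$res_j)
}

#' Interaction densities of a structure
#'
#' Contacts per residue for each of the six interaction classes.
#'
#' @param contacts Contact tibble from [detect_interactions()].
#' @param n_residues Number of residues in the structure.
#' @return Tibble with `type` and `density` for all six classes (0 where no
#'   contact).
#' @export
interaction_density <- function(contacts, n_residues) {
  stopifnot(n_residues > 0)
  types <- c("aromatic_aromatic", "aromatic_sulfur", "cation_pi", "ionic",
             "disulfide", "hydrophobic")
  counts <- table(factor(contacts$type, levels = types))
  tibble::tibble(type = types, density = as.numeric(counts) / n_residues)
}
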