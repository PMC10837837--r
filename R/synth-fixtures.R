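# Deterministic structure fixtures with machine-readable truth: two-residue
# contact fixtures at an exact requested distance, and a core/surface sphere
# fixture whose construction guarantees the relative-accessibility partition.

CONTACT_PAIRS <- list(
  hydrophobic = c("ALA", "ALA"),
  ionic = c("ARG", "ASP"),
  aromatic_aromatic = c("PHE", "PHE"),
  aromatic_sulfur = c("MET", "PHE"),
  cation_pi = c("LYS", "PHE"),
  disulfide = c("CYS", "CYS")
)

contact_metric <- function(type, g1, g2, thresholds) {
  switch(type,
    hydrophobic = min_pair_dist(g1$carbons, g2$carbons),
    ionic = vnorm(g1$cation - g2$anion),
    aromatic_aromatic = vnorm(g1$ring - g2$ring),
    aromatic_sulfur = vnorm(g1$sulfur - g2$ring),
    cation_pi = vnorm(g1$cpi - g2$ring),
    disulfide = vnorm(g1$sulfur - g2$sulfur))
}

contact_satisfied <- function(type, distance, thresholds = interaction_thresholds()) {
  switch(type,
    hydrophobic = distance <= thresholds$hydrophobic,
    ionic = distance <= thresholds$ionic,
    aromatic_aromatic = distance >= thresholds$aromatic_min &&
      distance <= thresholds$aromatic_max,
    aromatic_sulfur = distance <= thresholds$aromatic_sulfur,
    cation_pi = distance <= thresholds$cation_pi,
    disulfide = distance <= thresholds$disulfide)
}

#' Build a two-residue interaction fixture at an exact distance
#'
#' Places two residues of the types defining `type` at the ends of a
#' glycine-spacered peptide (so the sequence separation is at least 2) and
#' rigidly translates the second residue so that the type's defining distance
#' (e.g. SG-SG for disulfide, ring-centroid separation for
#' aromatic-aromatic) equals `distance` exactly. The truth flag states
#' whether that distance satisfies the default criterion.
#'
#' @param type One of the six interaction classes.
#' @param distance Requested defining distance (Angstrom), > 0.
#' @param thresholds Criteria used for the truth flag.
#' @return List with `atoms`, `type`, `distance`, `expected` (logical),
#'   `res_i`, `res_j`.
#' @export
#' @examples
#' fx <- make_contact_fixture("disulfide", 2.0)
#' fx$expected
make_contact_fixture <- function(type, distance,
                                 thresholds = interaction_thresholds()) {
  if (!type %in% names(CONTACT_PAIRS)) {
    abort(paste0("unknown interaction type: ", type))
  }
  stopifnot(distance > 0)
  pair <- CONTACT_PAIRS[[type]]
  atoms <- build_peptide(c(pair[1], "GLY", "GLY", "GLY", pair[2]), "extended")
  rg <- residue_groups(atoms)
  g1 <- rg$groups[[1]]; g2 <- rg$groups[[5]]
  m <- contact_metric(type, g1, g2, thresholds)
  # translate residue 5 along the line joining the two group centres
  centre1 <- switch(type, hydrophobic = colMeans(g1$carbons),
                    ionic = g1$cation, aromatic_aromatic = g1$ring,
                    aromatic_sulfur = g1$sulfur, cation_pi = g1$cpi,
                    disulfide = g1$sulfur)
  centre2 <- switch(type, hydrophobic = colMeans(g2$carbons),
                    ionic = g2$anion, aromatic_aromatic = g2$ring,
                    aromatic_sulfur = g2$ring, cation_pi = g2$ring,
                    disulfide = g2$sulfur)
  u <- unit(centre2 - centre1)
  shift <- (distance - m) * u
  sel <- atoms$residue_index == 5
  atoms$x[sel] <- atoms$x[sel] + shift[1]
  atoms$y[sel] <- atoms$y[sel] + shift[2]
  atoms$z[sel] <- atoms$z[sel] + shift[3]
  list(atoms = atoms, type = type, distance = distance,
       expected = contact_satisfied(type, distance, thresholds),
       res_i = 1L, res_j = 5L)
}

#' Build a core/surface sphere fixture with known truth
#'
#' Core residues are packed at the centre; surface residues form a dense
#' shell around them with side chains pointing outward. The shell occludes
#' the core so thoroughly that core residues fall far below the 20% relative
#' accessibility threshold while shell residues stay far above it; the truth
#' labels are recorded per residue.
#'
#' @param n_core,n_surface Residue counts (each >= 1).
#' @param shell_radius Radius of the shell (Angstrom).
#' @return List with `atoms` and `truth` (tibble `residue_index`, `region`).
#' @export
make_core_surface_fixture <- function(n_core, n_surface, shell_radius = 6) {
  if (n_core < 1 || n_surface < 1) abort("need at least one residue per region")
  rows <- list()
  add <- function(i, name, xyz) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      residue_index = i, residue_type = "ALA", atom_name = name,
      element = substr(name, 1, 1), x = xyz[1], y = xyz[2], z = xyz[3])
  }
  core_dirs <- sphere_points(n_core)
  for (i in seq_len(n_core)) {
    q <- core_dirs[i, ]
    add(i, "CA", 0.9 * q)
    add(i, "CB", 1.8 * q)
  }
  shell_dirs <- sphere_points(n_surface)
  for (j in seq_len(n_surface)) {
    i <- n_core + j
    q <- shell_dirs[j, ]
    ref <- if (abs(q[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- unit(cross3(q, ref))
    add(i, "N", shell_radius * q + 1.4 * t1)
    add(i, "CA", shell_radius * q)
    add(i, "C", shell_radius * q - 1.4 * t1)
    add(i, "CB", (shell_radius + 1.6) * q)
  }
  atoms <- dplyr::bind_rows(rows)
  truth <- tibble::tibble(
    residue_index = seq_len(n_core + n_surface),
    region = rep(c("core", "surface"), c(n_core, n_surface)))
  list(atoms = atoms, truth = truth)
}
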