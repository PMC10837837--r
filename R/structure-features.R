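# Structure-level feature assembly: per-residue annotation (SASA, RSA,
# region, secondary structure), region/SS-stratified composition, and
# aggregation of externally computed per-residue stability scores.

#' Annotate every residue of a structure
#'
#' Runs the SASA engine, the core/surface partition and the torsion-window
#' secondary-structure assigner and joins the results per residue.
#'
#' @inheritParams compute_sasa
#' @param core_rsa Core threshold on RSA.
#' @return Tibble with `residue_index`, `residue_type`, `sasa`, `rsa`,
#'   `region`, `phi`, `psi`, `ss`.
#' @export
annotate_residues <- function(atoms, probe = 1.4, n_points = 960, core_rsa = 0.20) {
  rs <- residue_sasa(compute_sasa(atoms, probe = probe, n_points = n_points))
  rs <- relative_accessibility(rs, core_rsa = core_rsa,
                               max_asa = max_asa_table(probe, n_points))
  ss <- assign_secondary_structure(atoms)
  dplyr::left_join(rs, ss[, c("residue_index", "phi", "psi", "ss")],
                   by = "residue_index") |>
    dplyr::arrange(.data$residue_index)
}

#' Structure feature set of one protein
#'
#' Per-residue annotations, interaction contacts and per-type interaction
#' densities for a single-chain structure.
#'
#' @inheritParams annotate_residues
#' @param thresholds Interaction criteria ([interaction_thresholds()]).
#' @param protein_id Identifier carried into the outputs.
#' @return List with `residues`, `contacts`, `densities` tibbles (each
#'   carrying `protein_id`).
#' @export
structure_features <- function(atoms, protein_id = "protein",
                               probe = 1.4, n_points = 960, core_rsa = 0.20,
                               thresholds = interaction_thresholds()) {
  residues <- annotate_residues(atoms, probe, n_points, core_rsa)
  contacts <- detect_interactions(atoms, thresholds)
  densities <- interaction_density(contacts, nrow(residues))
  list(
    residues = dplyr::mutate(residues, protein_id = protein_id, .before = 1),
    contacts = dplyr::mutate(contacts, protein_id = protein_id, .before = 1),
    densities = dplyr::mutate(densities, protein_id = protein_id, .before = 1)
  )
}

#' Region- and secondary-structure-stratified composition
#'
#' Amino-acid frequency vectors for the six strata (core/surface x H/E/C)
#' pooled over the supplied residues, plus the overall secondary-structure
#' fractions. Strata with fewer than `min_support` residues are flagged.
#'
#' @param residues Residue annotation tibble (e.g. pooled
#'   [annotate_residues()] output over many structures) with
#'   `residue_type`, `region`, `ss`.
#' @param min_support Flagging threshold for thin strata.
#' @return List with `strata` (tibble: `region`, `ss`, `n`, `low_support`,
#'   list column `f` of 20-vectors summing to 1) and `ss_fractions`.
#' @export
stratified_composition <- function(residues, min_support = 100) {
  one <- AA_ONE[residues$residue_type]
  keep <- !is.na(one)
  df <- tibble::tibble(aa = unname(one[keep]),
                       region = residues$region[keep], ss = residues$ss[keep])
  grid <- tidyr::expand_grid(region = c("core", "surface"), ss = c("H", "E", "C"))
  strata <- grid |>
    dplyr::mutate(purrr::map2_dfr(.data$region, .data$ss, function(rg, s) {
      sel <- df$aa[df$region == rg & df$ss == s]
      n <- length(sel)
      f <- if (n > 0) {
        as.numeric(table(factor(sel, levels = AA_ORDER))) / n
      } else {
        rep(NA_real_, 20)
      }
      tibble::tibble(n = n, f = list(setNames(f, AA_ORDER)))
    })) |>
    dplyr::mutate(low_support = .data$n < min_support)
  ssf <- table(factor(df$ss, levels = c("H", "E", "C")))
  list(strata = strata,
       ss_fractions = setNames(as.numeric(ssf) / max(1, sum(ssf)), c("H", "E", "C")))
}

#' Aggregate per-residue stability scores
#'
#' Means of externally computed per-residue stability scores (kcal/mol;
#' negative = stabilising) per protein, and per clade when a clade mapping is
#' given, with the percentage change of each clade mean against a reference
#' clade.
#'
#' @param scores Tibble with `protein_id`, `residue_index`, `S`.
#' @param clades Optional tibble `protein_id` -> `clade`.
#' @param reference Reference clade label for percentage changes.
#' @return Tibble of per-protein means, or per-clade means with
#'   `pct_change_vs_reference` when `clades` is given.
#' @export
aggregate_stability <- function(scores, clades = NULL, reference = NULL) {
  if (nrow(scores) == 0) {
    warn("empty stability table")
    return(tibble::tibble(protein_id = character(), mean_S = numeric()))
  }
  per_protein <- scores |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(mean_S = mean(.data$S, na.rm = TRUE), .groups = "drop")
  if (is.null(clades)) return(per_protein)
  per_clade <- per_protein |>
    dplyr::inner_join(clades, by = "protein_id") |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(mean_S = mean(.data$mean_S), n_proteins = dplyr::n(),
                     .groups = "drop")
  if (!is.null(reference)) {
    ref <- per_clade$mean_S[per_clade$clade == reference]
    if (length(ref) != 1) abort(paste0("reference clade not found: ", reference))
    per_clade <- dplyr::mutate(
      per_clade, pct_change_vs_reference = 100 * (.data$mean_S - ref) / abs(ref))
  }
  per_clade
}

#' Match a stability table against a structure
#'
#' Counts score rows whose residue indices are absent from the structure and
#' warns; returns the matching rows.
#'
#' @param scores Tibble with `residue_index` (single protein).
#' @param residues Residue annotation tibble of the structure.
#' @return The matching score rows.
#' @export
match_stability <- function(scores, residues) {
  ok <- scores$residue_index %in% residues$residue_index
  if (any(!ok)) {
    warn(paste0(sum(!ok), " stability score(s) with residue index absent from structure"))
  }
  scores[ok, , drop = FALSE]
}
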