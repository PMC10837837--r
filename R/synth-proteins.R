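# Seeded protein-family generator: families of homologous proteins with a
# planted within-family pairwise identity and per-clade amino-acid
# composition shifts, optionally restricted to designated surface positions.
#
# Two design points keep the planted truth tight at desk scale:
#  * the per-member substitution rate is DERIVED from the target pairwise
#    identity (two members differing from the ancestor at rate s are
#    identical at roughly (1-s)^2 plus coincidences, so s != 1 - identity);
#  * compositions are variance-controlled: ancestors and substitution fills
#    use exact-count multisets (randomised systematic rounding), so every
#    member carries its clade's planted composition up to integer rounding
#    and the clade mean is unbiased for the planted target.

tilt_composition <- function(p, multipliers) {
  g <- p
  if (length(multipliers) > 0) {
    bad <- setdiff(names(multipliers), names(p))
    if (length(bad) > 0) abort(paste0("unknown amino acid(s) in shift: ",
                                      paste(bad, collapse = ", ")))
    g[names(multipliers)] <- p[names(multipliers)] * multipliers
    nulls <- setdiff(names(p), names(multipliers))
    spare <- 1 - sum(g[names(multipliers)])
    if (spare <= 0) abort("shift vector drives null frequencies negative")
    g[nulls] <- p[nulls] * spare / sum(p[nulls])
  }
  if (any(g <= 0)) abort("shift vector produces non-positive frequency")
  g / sum(g)
}

# substitution rate giving a target within-family pairwise identity, for
# coincidence probability c = sum(p^2)
pairwise_rate <- function(identity, coincidence) {
  disc <- 1 - (1 - identity) / (1 - coincidence)
  if (disc < 0) abort("identity target unreachable")
  1 - sqrt(disc)
}

exact_multiset <- function(n, probs) {
  if (n == 0) return(character(0))
  counts <- largest_remainder(n, probs)
  sample(rep(names(probs), counts))
}


#' Configuration of the synthetic protein-family generator
#'
#' Defaults are the study conditions: four clades, 20 families of 10 members
#' per clade (200 proteins per clade), protein length 300 with half the
#' positions designated surface, within-family pairwise identity
#' 0.80 +/- 0.08, and surface-restricted planted shifts following the
#' adaptation signatures — Lys up in the psychrophilic clade (raising
#' Lys/Arg ~8%), Asp and Glu up in the halophilic clade (~10%), and Glu
#' raised over Asp in the thermophilic clade (Glu/Asp ~10% over its
#' reference).
#'
#' @param clades Clade labels.
#' @param shifts Named list (per clade) of named multipliers applied to the
#'   background composition at shifted positions, e.g. `c(D = 1.10)`.
#' @param surface_only Apply shifts at surface positions only.
#' @param n_families,members_per_clade,length Family structure.
#' @param surface_frac Fraction of positions designated surface.
#' @param identity,identity_sd Within-family pairwise identity target and its
#'   between-family spread (truncated to `[0.55, 0.95]`).
#' @param base Background amino-acid composition (named 20-vector).
#' @return A config list for [make_protein_families()].
#' @export
protein_sim_config <- function(
    clades = c("Ia", "Ib", "IIa", "IIb"),
    shifts = list(Ia = NULL,
                  Ib = c(K = 1.08),
                  IIa = c(D = 1.10, E = 1.10),
                  IIb = c(D = 1.10, E = 1.21)),
    surface_only = TRUE,
    n_families = 20, members_per_clade = 10, length = 300,
    surface_frac = 0.5,
    identity = 0.80, identity_sd = 0.08,
    base = aa_background_vec()) {
  as.list(environment())
}

#' Generate synthetic protein families with planted signatures
#'
#' Each family has an exact-composition ancestor; each member copies the
#' ancestor and substitutes a derived fraction of positions so that (i) the
#' within-family pairwise identity matches the family's planted target and
#' (ii) the member's composition at surface (and core) positions matches its
#' clade's planted composition up to integer rounding. Truth records the
#' surface masks, per-family identities and planted clade compositions.
#' Pure function of `(config, seed)`.
#'
#' @param config From [protein_sim_config()].
#' @param seed Integer seed.
#' @return List with `proteins` (tibble: `protein_id`, `isolate_id`, `clade`,
#'   `family_id`, `sequence`) and `truth` (list: `surface_masks`,
#'   `family_identity`, `clade_surface_composition`,
#'   `clade_core_composition`, `planted_d`).
#' @export
make_protein_families <- function(config = protein_sim_config(), seed = 1) {
  withr::with_seed(seed, make_protein_families_impl(config))
}

make_protein_families_impl <- function(cf) {
  p <- cf$base
  comps_surface <- lapply(cf$clades, function(cl) {
    tilt_composition(p, cf$shifts[[cl]] %||% numeric(0))
  })
  names(comps_surface) <- cf$clades
  comps_core <- if (cf$surface_only) {
    setNames(rep(list(p), length(cf$clades)), cf$clades)
  } else {
    comps_surface
  }
  coincidence <- sum(p^2)

  L <- cf$length
  n_surf <- round(L * cf$surface_frac)
  rows <- list()
  masks <- list()
  fam_ident <- numeric(cf$n_families)

  for (f in seq_len(cf$n_families)) {
    fam_id <- sprintf("F%03d", f)
    t_f <- min(0.95, max(0.55, rnorm(1, cf$identity, cf$identity_sd)))
    fam_ident[f] <- t_f
    s <- pairwise_rate(t_f, coincidence)
    surf_pos <- sort(sample.int(L, n_surf))
    core_pos <- setdiff(seq_len(L), surf_pos)
    masks[[fam_id]] <- surf_pos

    anc <- character(L)
    anc[surf_pos] <- exact_multiset(length(surf_pos), p)
    anc[core_pos] <- exact_multiset(length(core_pos), p)

    # Substitute k_sub positions of the ancestor segment so that the member's
    # residue counts equal a randomised rounding of the clade target
    # composition. Positions are chosen so the kept residues never exceed the
    # target for any amino acid (residues the ancestor has in excess of the
    # target are substituted first); the remaining substituted positions are
    # uniform. The fill multiset is then the exact count difference, so the
    # member composition is unbiased for the planted target.
    derive_segment <- function(anc_seg, target_comp, k_sub) {
      n <- length(anc_seg)
      if (n == 0 || k_sub == 0) return(anc_seg)
      target <- rand_round_counts(n, target_comp)
      anc_counts <- table(factor(anc_seg, levels = names(target_comp)))
      mand <- pmax(0, as.numeric(anc_counts) - as.numeric(target))
      names(mand) <- names(target_comp)
      if (sum(mand) > k_sub) {  # substitution budget too small; trim (rare)
        mand <- largest_remainder(k_sub, mand / sum(mand))
      }
      sub_at <- integer(0)
      for (a in names(mand)[mand > 0]) {
        pos_a <- which(anc_seg == a)
        sub_at <- c(sub_at, pos_a[sample.int(length(pos_a), mand[[a]])])
      }
      rest <- setdiff(seq_len(n), sub_at)
      extra <- k_sub - length(sub_at)
      if (extra > 0) sub_at <- c(sub_at, rest[sample.int(length(rest), extra)])
      kept_counts <- table(factor(anc_seg[-sub_at], levels = names(target_comp)))
      fill <- pmax(0, as.numeric(target) - as.numeric(kept_counts))
      if (sum(fill) != k_sub) {  # only reachable via the trimmed branch
        fill <- largest_remainder(k_sub, if (sum(fill) > 0) fill / sum(fill)
                                         else target_comp)
      }
      out <- anc_seg
      out[sub_at] <- sample(rep(names(target_comp), fill))
      out
    }

    for (cl in cf$clades) {
      for (m in seq_len(cf$members_per_clade)) {
        mem <- anc
        mem[surf_pos] <- derive_segment(anc[surf_pos], comps_surface[[cl]],
                                        round(s * length(surf_pos)))
        mem[core_pos] <- derive_segment(anc[core_pos], comps_core[[cl]],
                                        round(s * length(core_pos)))
        rows[[length(rows) + 1]] <- tibble::tibble(
          protein_id = sprintf("%s_%02d_%s", cl, m, fam_id),
          isolate_id = sprintf("%s_%02d", cl, m),
          clade = cl, family_id = fam_id,
          sequence = paste(mem, collapse = ""))
      }
    }
  }

  planted_d <- lapply(seq_len(nrow(default_contrasts())), function(i) {
    ct <- default_contrasts()[i, ]
    if (!(ct$target %in% cf$clades && ct$reference %in% cf$clades)) return(NULL)
    composition_signature(comps_surface[[ct$target]], comps_surface[[ct$reference]])
  })
  names(planted_d) <- default_contrasts()$label

  list(
    proteins = dplyr::bind_rows(rows),
    truth = list(surface_masks = masks,
                 family_identity = setNames(fam_ident, names(masks)),
                 clade_surface_composition = comps_surface,
                 clade_core_composition = comps_core,
                 planted_d = planted_d[!vapply(planted_d, is.null, logical(1))])
  )
}

#' Per-protein amino-acid frequencies within a stratum
#'
#' Computes each generated protein's amino-acid frequency vector restricted
#' to its family's designated surface (or core) positions, using the
#' generator truth masks, in the long format [run_contrasts()] consumes.
#'
#' @param sim Output of [make_protein_families()].
#' @param stratum `"surface"` or `"core"`.
#' @return Long tibble with `id`, `clade`, `feature` (amino acid), `value`.
#' @export
stratum_frequencies <- function(sim, stratum = c("surface", "core")) {
  stratum <- match.arg(stratum)
  masks <- sim$truth$surface_masks
  purrr::pmap_dfr(
    sim$proteins[, c("protein_id", "clade", "family_id", "sequence")],
    function(protein_id, clade, family_id, sequence) {
      ch <- strsplit(sequence, "")[[1]]
      pos <- masks[[family_id]]
      if (stratum == "core") pos <- setdiff(seq_along(ch), pos)
      f <- table(factor(ch[pos], levels = AA_ORDER)) / length(pos)
      tibble::tibble(id = protein_id, clade = clade,
                     feature = AA_ORDER, value = as.numeric(f))
    })
}
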