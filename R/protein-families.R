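# Protein family clustering and conservation. Pairwise global alignment is
# delegated to Biostrings; the clustering itself is a greedy centroid pass
# with explicit, configurable scoring so results are reproducible at desk
# scale.

aln_submat <- function(match = 1, mismatch = 0) {
  letters <- c(AA_ORDER, "X", "B", "Z", "U", "*")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Global pairwise alignment identity and coverage
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, gap open -10,
#' gap extend -0.5 by default). Identity is the fraction of identical columns
#' over the alignment length excluding terminal gaps; coverage is the
#' non-terminal-gap span divided by the shorter sequence length.
#'
#' @param a,b Protein sequences (single strings).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring constants.
#' @return Tibble with `identity`, `coverage`, `alignment_length`.
#' @export
#' @examples
#' align_identity("AAAA", "AAAT")
align_identity <- function(a, b, match = 1, mismatch = 0,
                           gap_open = 10, gap_extend = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = aln_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | pb == "-"
  non_gap <- which(!gap)
  if (length(non_gap) == 0) {
    return(tibble::tibble(identity = 0, coverage = 0, alignment_length = 0L))
  }
  # terminal-gap columns: before the first or after the last column where
  # both sequences have a residue
  span <- seq(min(non_gap), max(non_gap))
  ident <- mean(pa[span] == pb[span])
  cov <- length(span) / min(nchar(a), nchar(b))
  tibble::tibble(identity = ident, coverage = cov,
                 alignment_length = length(span))
}

#' Greedy centroid clustering of proteins into families
#'
#' Proteins are sorted by decreasing length (ties broken by lexicographic
#' id) and processed in order: each protein joins the first existing family
#' whose representative it matches at `min_identity` identity and
#' `min_coverage` coverage under [align_identity()], otherwise it founds a
#' new family with itself as representative. Deterministic given the stated
#' ordering.
#'
#' @param proteins Tibble with columns `protein_id`, `sequence` and
#'   optionally `isolate_id`.
#' @param min_identity Identity cut-off (fraction).
#' @param min_coverage Coverage cut-off (fraction).
#' @inheritParams align_identity
#' @return The input with `family_id` and `is_representative` appended.
#' @export
cluster_families <- function(proteins, min_identity = 0.50, min_coverage = 0.80,
                             match = 1, mismatch = 0, gap_open = 10,
                             gap_extend = 0.5) {
  stopifnot(nrow(proteins) >= 1)
  ord <- order(-nchar(proteins$sequence), proteins$protein_id)
  reps <- integer(0)  # row indices (in ord-ed frame) of representatives
  fam <- integer(nrow(proteins))
  seqs <- proteins$sequence[ord]
  for (i in seq_along(seqs)) {
    assigned <- 0L
    for (r in seq_along(reps)) {
      hit <- align_identity(seqs[i], seqs[reps[r]], match, mismatch,
                            gap_open, gap_extend)
      if (hit$identity >= min_identity && hit$coverage >= min_coverage) {
        assigned <- r
        break
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, i)
      assigned <- length(reps)
    }
    fam[i] <- assigned
  }
  out <- proteins[ord, , drop = FALSE]
  out$family_id <- sprintf("F%04d", fam)
  out$is_representative <- seq_along(seqs) %in% reps
  out
}

#' Filter families by member count
#'
#' Keeps families with at least `min_members` members. The default threshold
#' is half the number of genomes (rounded up), the conservation-analysis
#' convention for "present in most of the pangenome".
#'
#' @param families Tibble with a `family_id` column (e.g. from
#'   [cluster_families()]).
#' @param n_genomes Number of genomes behind the protein set (used for the
#'   default threshold).
#' @param min_members Explicit member-count threshold; overrides `n_genomes`.
#' @return The input restricted to retained families.
#' @export
filter_families <- function(families, n_genomes = NULL, min_members = NULL) {
  if (is.null(min_members)) {
    if (is.null(n_genomes)) abort("give n_genomes or min_members")
    min_members <- ceiling(n_genomes / 2)
  }
  dplyr::group_by(families, .data$family_id) |>
    dplyr::filter(dplyr::n() >= min_members) |>
    dplyr::ungroup()
}

#' Mean pairwise identity within families
#'
#' Average over all unordered member pairs of the global-alignment identity
#' defined in [align_identity()]. Families with fewer than two members get
#' missing values.
#'
#' @inheritParams filter_families
#' @inheritParams align_identity
#' @return Tibble with `family_id`, `n_members`, `mean_identity`,
#'   `sd_identity` (percent).
#' @export
mean_pairwise_identity <- function(families, match = 1, mismatch = 0,
                                   gap_open = 10, gap_extend = 0.5) {
  families |>
    dplyr::group_by(.data$family_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 2) {
        return(tibble::tibble(n_members = n, mean_identity = NA_real_,
                              sd_identity = NA_real_))
      }
      pairs <- utils::combn(n, 2)
      ident <- vapply(seq_len(ncol(pairs)), function(k) {
        align_identity(df$sequence[pairs[1, k]], df$sequence[pairs[2, k]],
                       match, mismatch, gap_open, gap_extend)$identity
      }, numeric(1))
      tibble::tibble(n_members = n, mean_identity = 100 * mean(ident),
                     sd_identity = 100 * sd(ident))
    }) |>
    dplyr::ungroup()
}
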