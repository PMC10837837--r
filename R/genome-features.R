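# Per-isolate genome-scale features: GC content, positional GC, codon usage,
# N50, the assembly QC gate, AAI deduplication and clade summaries.

count_bases <- function(sequence) {
  s <- Biostrings::DNAStringSet(toupper(sequence))
  f <- Biostrings::alphabetFrequency(s, baseOnly = TRUE)
  colSums(f)[c("A", "C", "G", "T")]
}

#' GC content of a nucleotide sequence
#'
#' (G+C)/(A+C+G+T), case-insensitive. Ambiguity codes (including N) are
#' excluded from both numerator and denominator. If a sequence has no
#' unambiguous base the result is `NA` with a warning.
#'
#' @param sequence Character vector of nucleotide sequences; all are pooled.
#' @return GC fraction in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' gc_content("ATGC")
gc_content <- function(sequence) {
  n <- count_bases(sequence)
  tot <- sum(n)
  if (tot == 0) {
    warn("no unambiguous bases; GC content undefined")
    return(NA_real_)
  }
  unname((n[["G"]] + n[["C"]]) / tot)
}

#' @rdname gc_content
#' @export
at_content <- function(sequence) {
  n <- count_bases(sequence)
  tot <- sum(n)
  if (tot == 0) {
    warn("no unambiguous bases; AT content undefined")
    return(NA_real_)
  }
  unname((n[["A"]] + n[["T"]]) / tot)
}

#' GC content at the three codon positions
#'
#' Pools all coding sequences of an isolate (already strand-resolved, i.e.
#' given 5'->3') and returns the GC fraction at codon positions 1, 2 and 3.
#' Stop codons are included; a trailing partial codon is dropped with a
#' warning; ambiguity codes are excluded as in [gc_content()].
#'
#' @param cds_sequences Character vector of CDS nucleotide sequences.
#' @return Named numeric vector `c(GC1=, GC2=, GC3=)`; `NA`s for an empty set.
#' @export
#' @examples
#' positional_gc("ATGGCATAA")
positional_gc <- function(cds_sequences) {
  cds_sequences <- cds_sequences[!is.na(cds_sequences) & nzchar(cds_sequences)]
  if (length(cds_sequences) == 0) {
    warn("empty CDS set; positional GC undefined")
    return(c(GC1 = NA_real_, GC2 = NA_real_, GC3 = NA_real_))
  }
  len <- nchar(cds_sequences)
  if (any(len %% 3 != 0)) {
    warn(paste0(sum(len %% 3 != 0), " CDS with length not a multiple of 3; ",
                "trailing partial codon dropped"))
  }
  keep <- len - len %% 3
  chars <- strsplit(substr(toupper(cds_sequences), 1, keep), "")
  gc_at <- vapply(1:3, function(pos) {
    b <- unlist(lapply(chars, function(x) x[seq.int(pos, length(x), by = 3)]))
    b <- b[b %in% c("A", "C", "G", "T")]
    if (length(b) == 0) return(NA_real_)
    mean(b %in% c("G", "C"))
  }, numeric(1))
  setNames(gc_at, c("GC1", "GC2", "GC3"))
}

codon_split <- function(cds_sequences) {
  cds_sequences <- cds_sequences[!is.na(cds_sequences) & nzchar(cds_sequences)]
  len <- nchar(cds_sequences)
  keep <- len - len %% 3
  unlist(lapply(substr(toupper(cds_sequences), 1, keep), function(s) {
    substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
  }))
}

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16), rep(rep(b, each = 4), times = 4), rep(b, times = 16))
}

#' Codon usage of a pooled CDS set
#'
#' In `frequency` mode the 64-long vector sums to 1 over counted codons. In
#' `RSCU` mode each codon count is divided by the mean count of its synonymous
#' family under the standard genetic code (stop codons form their own family);
#' single-codon families have RSCU 1 when present. Codons containing
#' ambiguity codes are skipped.
#'
#' @inheritParams positional_gc
#' @param mode `"frequency"` or `"RSCU"`.
#' @return Named 64-long numeric vector (codon -> value); all-`NA` on empty
#'   input.
#' @export
codon_usage <- function(cds_sequences, mode = c("frequency", "RSCU")) {
  mode <- match.arg(mode)
  codons <- all_codons()
  cd <- codon_split(cds_sequences)
  cd <- cd[cd %in% codons]
  if (length(cd) == 0) {
    warn("no countable codons; codon usage undefined")
    return(setNames(rep(NA_real_, 64), codons))
  }
  counts <- table(factor(cd, levels = codons))
  if (mode == "frequency") {
    return(setNames(as.numeric(counts) / sum(counts), codons))
  }
  aa <- Biostrings::GENETIC_CODE[codons]
  fam_mean <- tapply(as.numeric(counts), aa, mean)[aa]
  rscu <- ifelse(fam_mean > 0, as.numeric(counts) / fam_mean, 0)
  setNames(as.numeric(rscu), codons)
}

#' N50 of a contig length set
#'
#' The smallest contig length `L` such that contigs of length `>= L` sum to at
#' least half the total assembly length. Order-invariant; always equal to one
#' of the input lengths.
#'
#' @param contig_lengths Positive integer vector of contig lengths (bp).
#' @return N50 in bp.
#' @export
#' @examples
#' n50(c(100, 200, 300, 400))
n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0) abort("empty contig length set")
  if (any(contig_lengths <= 0)) abort("contig lengths must be positive")
  len <- sort(contig_lengths, decreasing = TRUE)
  len[which(cumsum(len) >= sum(len) / 2)[1]]
}

#' Assembly quality-control gate
#'
#' A genome fails if ANY criterion is violated: more than `max_contigs`
#' contigs, N50 below `min_n50`, completeness below `min_completeness`, or
#' contamination above `max_contamination`. Defaults follow common practice
#' for high-quality isolate genomes (300 contigs, 20 kb, 95%, 5%). A missing
#' metric fails with reason `"missing metric"`.
#'
#' @param metrics Tibble with columns `isolate_id`, `n_contigs`, `N50`,
#'   `completeness`, `contamination`.
#' @param max_contigs,min_n50,min_completeness,max_contamination Thresholds.
#' @return The input with logical `pass` and list column `reasons` appended.
#' @export
qc_filter <- function(metrics, max_contigs = 300, min_n50 = 20000,
                      min_completeness = 95, max_contamination = 5) {
  stopifnot(all(c("isolate_id", "n_contigs", "N50", "completeness",
                  "contamination") %in% names(metrics)))
  reasons <- purrr::pmap(
    metrics[, c("n_contigs", "N50", "completeness", "contamination")],
    function(n_contigs, N50, completeness, contamination) {
      vals <- c(n_contigs, N50, completeness, contamination)
      if (anyNA(vals)) return("missing metric")
      r <- character(0)
      if (n_contigs > max_contigs) r <- c(r, paste0("contigs>", max_contigs))
      if (N50 < min_n50) r <- c(r, paste0("N50<", min_n50))
      if (completeness < min_completeness) {
        r <- c(r, paste0("completeness<", min_completeness))
      }
      if (contamination > max_contamination) {
        r <- c(r, paste0("contamination>", max_contamination))
      }
      r
    })
  dplyr::mutate(metrics, pass = lengths(reasons) == 0, reasons = reasons)
}

#' Deduplicate isolates by average amino-acid identity
#'
#' Builds a graph with an edge for every isolate pair whose AAI is at or above
#' `threshold` and keeps exactly one representative per connected component,
#' chosen by higher completeness, then lower contamination, then lexicographic
#' isolate id. The result is independent of input order, and rerunning on the
#' retained set is the identity.
#'
#' @param aai Symmetric numeric matrix of pairwise AAI percentages with
#'   isolate ids as dimnames (diagonal 100).
#' @param metadata Tibble with `isolate_id` and (optionally) `completeness`,
#'   `contamination` used for representative choice.
#' @param threshold Duplication threshold in percent.
#' @return Character vector of retained isolate ids, sorted.
#' @export
dedup_aai <- function(aai, metadata = NULL, threshold = 99.5) {
  stopifnot(is.matrix(aai), nrow(aai) == ncol(aai))
  if (max(abs(aai - t(aai))) > 1e-6) abort("AAI matrix is asymmetric beyond tolerance")
  ids <- rownames(aai)
  if (is.null(ids)) abort("AAI matrix must carry isolate ids as dimnames")
  comp <- setNames(rep(NA_real_, length(ids)), ids)
  cont <- setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(metadata)) {
    m <- metadata[match(ids, metadata$isolate_id), ]
    if ("completeness" %in% names(m)) comp[] <- m$completeness
    if ("contamination" %in% names(m)) cont[] <- m$contamination
  }
  adj <- aai >= threshold
  diag(adj) <- FALSE
  # connected components by repeated expansion
  comp_id <- seq_along(ids)
  repeat {
    new_id <- comp_id
    for (i in seq_along(ids)) {
      nb <- which(adj[i, ])
      if (length(nb) > 0) new_id[i] <- min(new_id[c(i, nb)])
    }
    if (identical(new_id, comp_id)) break
    comp_id <- new_id
  }
  keep <- vapply(split(seq_along(ids), comp_id), function(members) {
    ord <- order(-ifelse(is.na(comp[members]), -Inf, comp[members]),
                 ifelse(is.na(cont[members]), Inf, cont[members]),
                 ids[members])
    members[ord[1]]
  }, integer(1))
  sort(ids[keep])
}

#' Coding density
#'
#' Number of coding sequences per kilobase of genome.
#'
#' @param n_cds Number of CDS.
#' @param genome_size_bp Genome size in bp.
#' @return Genes per kb.
#' @export
coding_density <- function(n_cds, genome_size_bp) {
  stopifnot(all(genome_size_bp > 0))
  n_cds / (genome_size_bp / 1000)
}

#' Per-clade summary of a feature table
#'
#' Mean and sample standard deviation (n-1 denominator) of every numeric
#' feature per clade, with missing values excluded pairwise and the number of
#' non-missing observations reported per cell. Single-observation cells get a
#' missing sd. Clades absent from `feature_table` are dropped with a warning.
#'
#' @param feature_table Tibble with `isolate_id` and numeric feature columns.
#' @param clades Tibble with `isolate_id`, `clade`.
#' @return Long tibble: `clade`, `feature`, `mean`, `sd`, `n`.
#' @export
clade_summary <- function(feature_table, clades) {
  empty <- setdiff(unique(clades$clade), unique(
    clades$clade[clades$isolate_id %in% feature_table$isolate_id]))
  if (length(empty) > 0) {
    warn(paste0("clade(s) without isolates omitted: ", paste(empty, collapse = ", ")))
  }
  joined <- dplyr::inner_join(feature_table, clades, by = "isolate_id")
  numcols <- names(joined)[vapply(joined, is.numeric, logical(1))]
  joined |>
    tidyr::pivot_longer(cols = dplyr::all_of(numcols), names_to = "feature") |>
    dplyr::group_by(.data$clade, .data$feature) |>
    dplyr::summarise(
      mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$value)) > 1) sd(.data$value, na.rm = TRUE) else NA_real_,
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Significance stars for p-values
#'
#' `ns` for p > .05, `*` for p <= .05, `**` for p <= .01, `***` for p <= .001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star classes.
#' @export
star_class <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Unpaired rank-sum contrast between two groups
#'
#' Two-sided Mann-Whitney test with tie correction; exact enumeration when
#' both groups have at most 8 observations and there are no ties, normal
#' approximation (with continuity correction) otherwise.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Tibble with `statistic` (U for `x`), `p_value`, `star`, `method`.
#' @export
#' @examples
#' rank_contrast(c(1, 2, 3), c(10, 11, 12))
rank_contrast <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    star = star_class(ht$p.value),
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Genome feature vector of one isolate
#'
#' Assembles the per-isolate genome-scale features: genome size, number of
#' CDS, coding density, CRISPR count, genome GC, positional GC of the pooled
#' CDS, and codon usage (frequency and RSCU).
#'
#' @param genome Genome tibble (`contig_id`, `sequence`).
#' @param annotations Annotation tibble for the same isolate.
#' @param isolate_id Isolate identifier carried into the output.
#' @return One-row tibble; codon vectors as list columns.
#' @export
genome_features <- function(genome, annotations, isolate_id = "isolate") {
  validate_genome(genome)
  size <- sum(nchar(genome$sequence))
  cds <- extract_feature_seq(annotations, genome, "CDS")$sequence
  pos <- positional_gc(cds)
  tibble::tibble(
    isolate_id = isolate_id,
    genome_size_bp = size,
    n_CDS = length(cds),
    coding_density = coding_density(length(cds), size),
    n_CRISPR = sum(annotations$feature_type == "CRISPR"),
    GC = gc_content(genome$sequence),
    GC1 = pos[["GC1"]], GC2 = pos[["GC2"]], GC3 = pos[["GC3"]],
    codon_frequency = list(codon_usage(cds, "frequency")),
    codon_rscu = list(codon_usage(cds, "RSCU"))
  )
}
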