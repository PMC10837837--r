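# Regulatory-element statistics: rRNA/tmRNA GC, promoter AT content, counts
# of insertion sequences, sRNAs, CRISPR loci and operons, operons per CDS.

#' GC content of an annotated feature class
#'
#' GC over the concatenation of all feature sequences of the requested type
#' (multi-copy features pooled; extraction is strand-resolved, which leaves GC
#' invariant but is enforced for consistency). Returns `NA` with a warning if
#' the genome has no feature of that type.
#'
#' @inheritParams extract_feature_seq
#' @param feature_type One of the annotation vocabulary, e.g. `"tmRNA"`.
#' @return GC fraction or `NA`.
#' @export
feature_gc <- function(annotations, genome, feature_type) {
  feats <- extract_feature_seq(annotations, genome, feature_type)
  if (nrow(feats) == 0) {
    warn(paste0("no ", feature_type, " features; GC undefined"))
    return(NA_real_)
  }
  gc_content(feats$sequence)
}

#' AT content of annotated promoters
#'
#' (A+T)/(A+C+G+T) pooled over all promoter intervals; ambiguity codes are
#' excluded from both counts. Promoter intervals come from an upstream
#' predictor and are consumed as annotation features.
#'
#' @inheritParams feature_gc
#' @return AT fraction or `NA` if no promoter is annotated.
#' @export
promoter_at <- function(annotations, genome) {
  feats <- extract_feature_seq(annotations, genome, "promoter")
  if (nrow(feats) == 0) {
    warn("no promoter features; AT content undefined")
    return(NA_real_)
  }
  at_content(feats$sequence)
}

#' Counts of regulatory elements
#'
#' Raw counts of insertion sequences, sRNAs, CRISPR loci and operons in an
#' annotation set.
#'
#' @param annotations Annotation tibble.
#' @return One-row tibble with columns `n_insertion_sequences`, `n_sRNA`,
#'   `n_CRISPR`, `n_operons`.
#' @export
element_counts <- function(annotations) {
  tibble::tibble(
    n_insertion_sequences = sum(annotations$feature_type == "insertion_sequence"),
    n_sRNA = sum(annotations$feature_type == "sRNA"),
    n_CRISPR = sum(annotations$feature_type == "CRISPR"),
    n_operons = sum(annotations$feature_type == "operon")
  )
}

#' Operons per coding sequence
#'
#' @param annotations Annotation tibble with at least one CDS.
#' @return Ratio of operon count to CDS count.
#' @export
operons_per_cds <- function(annotations) {
  n_cds <- sum(annotations$feature_type == "CDS")
  if (n_cds == 0) abort("zero CDS; operons per CDS undefined")
  sum(annotations$feature_type == "operon") / n_cds
}

#' Regulatory feature vector of one isolate
#'
#' Assembles the per-isolate regulatory statistics: rRNA GC, tmRNA GC,
#' promoter AT, element counts and operons per CDS. Features whose
#' annotation class is absent are reported as `NA`, never dropped.
#'
#' @inheritParams genome_features
#' @return One-row tibble.
#' @export
regulatory_features <- function(genome, annotations, isolate_id = "isolate") {
  counts <- element_counts(annotations)
  opc <- if (sum(annotations$feature_type == "CDS") > 0) {
    operons_per_cds(annotations)
  } else {
    NA_real_
  }
  dplyr::bind_cols(
    tibble::tibble(
      isolate_id = isolate_id,
      gc_rRNA = suppressWarnings(feature_gc(annotations, genome, "rRNA")),
      gc_tmRNA = suppressWarnings(feature_gc(annotations, genome, "tmRNA")),
      at_promoter = suppressWarnings(promoter_at(annotations, genome))
    ),
    counts,
    tibble::tibble(operons_per_CDS = opc)
  )
}
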