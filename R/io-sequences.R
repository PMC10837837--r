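# FASTA I/O and basic sequence arithmetic. Parsing is delegated to Biostrings;
# this layer adds the validation contract (order, ids, duplicates) and the
# tibble data model used throughout the package.

#' Read and write FASTA files
#'
#' `read_fasta()` returns the records of a FASTA file as a tibble in file
#' order. Record ids are taken up to the first whitespace of the header line;
#' sequence whitespace is stripped by the parser.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence` (uppercase).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "GGCC"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no records in FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  tibble::tibble(id = ids, sequence = toupper(as.character(set, use.names = FALSE)))
}

#' @rdname read_fasta
#' @param records A data frame with columns `id` and `sequence`.
#' @param width Line width for wrapped sequence lines.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "U")

#' Validate a genome record table
#'
#' A genome is a tibble with columns `contig_id` and `sequence`. Contig ids
#' must be unique, sequences non-empty, and the alphabet restricted to IUPAC
#' nucleotide codes (case-insensitive).
#'
#' @param genome A tibble with columns `contig_id`, `sequence`.
#' @return The validated genome, invisibly, sequences uppercased.
#' @export
validate_genome <- function(genome) {
  stopifnot(all(c("contig_id", "sequence") %in% names(genome)))
  if (anyDuplicated(genome$contig_id)) {
    abort("duplicate contig_id in genome record")
  }
  if (any(!nzchar(genome$sequence))) abort("empty contig sequence")
  genome$sequence <- toupper(genome$sequence)
  bad <- setdiff(unique(unlist(strsplit(genome$sequence, ""))), IUPAC_DNA)
  if (length(bad) > 0) {
    abort(paste0("invalid nucleotide code(s): ", paste(bad, collapse = ", ")))
  }
  invisible(genome)
}

#' Reverse-complement a nucleotide sequence
#'
#' IUPAC ambiguity codes are complemented according to the standard pairing
#' (e.g. R <-> Y); `N` maps to itself.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AACG")
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

#' Extract annotated feature sequences from a genome
#'
#' Returns feature sequences in 5'->3' orientation: minus-strand features are
#' reverse-complemented on extraction. Coordinates are 1-based inclusive as in
#' GFF3.
#'
#' @param annotations An annotation tibble (see [read_gff3()]).
#' @param genome A genome tibble (`contig_id`, `sequence`).
#' @param feature_type Optional filter; one of the annotation vocabulary.
#' @return The annotation rows, with a `sequence` column appended.
#' @export
extract_feature_seq <- function(annotations, genome, feature_type = NULL) {
  if (!is.null(feature_type)) {
    annotations <- dplyr::filter(annotations, .data$feature_type %in% .env$feature_type)
  }
  contig_seq <- setNames(genome$sequence, genome$contig_id)
  seqs <- substr(contig_seq[annotations$contig_id], annotations$start, annotations$end)
  minus <- annotations$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  dplyr::mutate(annotations, sequence = unname(seqs))
}
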