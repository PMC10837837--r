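# GFF3 I/O. Parsing/writing is delegated to rtracklayer; this layer maps the
# annotator's feature vocabulary onto the closed vocabulary used by the
# pipeline and validates coordinates against the genome.

#' Annotation feature vocabulary
#'
#' The closed set of feature types the pipeline consumes.
#'
#' @return Character vector of feature types.
#' @export
feature_vocabulary <- function() {
  c("CDS", "rRNA", "tmRNA", "sRNA", "insertion_sequence", "CRISPR",
    "operon", "promoter")
}

#' Default feature-type alias table
#'
#' Maps common annotator vocabularies (GFF3 `type` column values) onto the
#' closed feature vocabulary. Users can extend it to match their annotator,
#' e.g. for the attribute vocabulary their CRISPR caller emits.
#'
#' @param ... Named character entries to add or override, e.g.
#'   `"misc_RNA" = "sRNA"`.
#' @return Named character vector: names are annotator types, values are
#'   vocabulary types.
#' @export
#' @examples
#' feature_aliases("repeat_region" = "CRISPR")
feature_aliases <- function(...) {
  base <- c(
    CDS = "CDS", rRNA = "rRNA", tmRNA = "tmRNA", sRNA = "sRNA",
    ncRNA = "sRNA", insertion_sequence = "insertion_sequence",
    insertion_sequence_element = "insertion_sequence",
    mobile_genetic_element = "insertion_sequence",
    CRISPR = "CRISPR", direct_repeat = "CRISPR",
    operon = "operon", promoter = "promoter"
  )
  extra <- c(...)
  if (length(extra) > 0) base[names(extra)] <- unname(extra)
  bad <- setdiff(unique(unname(base)), feature_vocabulary())
  if (length(bad) > 0) {
    abort(paste0("alias target(s) outside the feature vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  base
}

#' Read an annotation set from a GFF3 file
#'
#' Coordinates are kept 1-based inclusive as in GFF3. Feature types are mapped
#' through `aliases`; records whose type has no alias are skipped with a
#' warning. Each record must fall inside a contig of `genome`.
#'
#' @param path Path to a GFF3 file.
#' @param genome Genome tibble (`contig_id`, `sequence`) the annotations refer to.
#' @param aliases Alias table from [feature_aliases()].
#' @return A tibble with columns `feature_type`, `contig_id`, `start`, `end`,
#'   `strand`, `attributes` (list column of named character vectors).
#' @export
read_gff3 <- function(path, genome, aliases = feature_aliases()) {
  gr <- rtracklayer::import(path, format = "gff3")
  # line number of each record, for coordinate error messages
  raw <- readLines(path)
  rec_lines <- which(!startsWith(raw, "#") & nzchar(trimws(raw)))
  if (length(rec_lines) < length(gr)) rec_lines <- seq_along(gr)  # defensive

  type <- as.character(gr$type)
  known <- type %in% names(aliases)
  if (any(!known)) {
    warn(paste0("skipping ", sum(!known), " record(s) with unmapped feature type(s): ",
                paste(unique(type[!known]), collapse = ", ")))
  }
  idx <- which(known)
  ann <- tibble::tibble(
    feature_type = unname(aliases[type[idx]]),
    contig_id = as.character(GenomicRanges::seqnames(gr))[idx],
    start = GenomicRanges::start(gr)[idx],
    end = GenomicRanges::end(gr)[idx],
    strand = as.character(GenomicRanges::strand(gr))[idx],
    attributes = purrr::map(idx, function(i) {
      m <- S4Vectors::mcols(gr)[i, setdiff(names(S4Vectors::mcols(gr)), "type"),
                                drop = FALSE]
      v <- vapply(as.list(m), function(x) {
        x <- unlist(x)
        if (length(x) == 0 || all(is.na(x))) NA_character_ else paste(x, collapse = ",")
      }, character(1))
      v[!is.na(v)]
    })
  )
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  validate_annotations(ann, genome, line = rec_lines[idx])
  ann
}

#' Validate an annotation table against its genome
#'
#' Checks the closed vocabulary, strand codes, and that
#' `1 <= start <= end <= contig length` for every record.
#'
#' @inheritParams extract_feature_seq
#' @param line Optional record line numbers used in error messages.
#' @return The annotation tibble, invisibly.
#' @export
validate_annotations <- function(annotations, genome, line = NULL) {
  stopifnot(all(c("feature_type", "contig_id", "start", "end", "strand") %in%
                  names(annotations)))
  bad_type <- setdiff(unique(annotations$feature_type), feature_vocabulary())
  if (length(bad_type) > 0) {
    abort(paste0("feature type(s) outside vocabulary: ", paste(bad_type, collapse = ", ")))
  }
  if (!all(annotations$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  clen <- setNames(nchar(genome$sequence), genome$contig_id)
  unknown <- setdiff(unique(annotations$contig_id), names(clen))
  if (length(unknown) > 0) {
    abort(paste0("annotation contig(s) absent from genome: ",
                 paste(unknown, collapse = ", ")))
  }
  ok <- annotations$start >= 1 & annotations$start <= annotations$end &
    annotations$end <= clen[annotations$contig_id]
  if (any(!ok)) {
    i <- which(!ok)[1]
    where <- if (!is.null(line)) paste0(" (line ", line[i], ")") else paste0(" (record ", i, ")")
    abort(paste0("coordinates outside contig ", annotations$contig_id[i],
                 ": ", annotations$start[i], "..", annotations$end[i], where))
  }
  invisible(annotations)
}

#' @rdname read_gff3
#' @param annotations Annotation tibble to write.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(annotations, path, genome = NULL, source = "ecosig") {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$contig_id,
    ranges = IRanges::IRanges(start = annotations$start, end = annotations$end),
    strand = annotations$strand
  )
  gr$source <- source
  gr$type <- annotations$feature_type
  # CDS records need a phase column; generated CDS always start in frame
  gr$phase <- ifelse(annotations$feature_type == "CDS", 0L, NA_integer_)
  if (!is.null(annotations$attributes)) {
    keys <- unique(unlist(lapply(annotations$attributes, names)))
    for (k in keys) {
      S4Vectors::mcols(gr)[[k]] <-
        vapply(annotations$attributes, function(a) a[k] %||% NA_character_, character(1))
    }
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
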