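# Newick trees (via ape) and isolate metadata tables (via readr).

#' Read a phylogenomic tree from a Newick file
#'
#' Missing branch lengths default to 0 with a warning. Leaf labels must be
#' unique; they are matched against isolate ids downstream.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e))))
  if (is.null(tree)) abort(paste0("Newick parse error in ", path))
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warn("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  tree
}

#' Read an isolate metadata table
#'
#' A TSV with one row per isolate. `isolate_id` and `clade_label` are
#' required; recognised optional columns (`habitat`, `MAT`, `salinity`,
#' `completeness`, `contamination`, `n_contigs`, `is_type_strain`) are parsed
#' with a locale-independent decimal point, `NA` cells kept as missing.
#'
#' @param path Path to a tab-delimited file with a header line.
#' @return A tibble, one row per isolate.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"),
                        locale = readr::locale(decimal_mark = "."))
  required <- c("isolate_id", "clade_label")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required metadata column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(md$isolate_id)) abort("duplicate isolate_id in metadata")
  for (col in c("completeness", "contamination")) {
    if (col %in% names(md) &&
        any(md[[col]] < 0 | md[[col]] > 100, na.rm = TRUE)) {
      abort(paste0(col, " must lie in [0, 100]"))
    }
  }
  if ("salinity" %in% names(md) && any(md$salinity < 0, na.rm = TRUE)) {
    abort("salinity must be non-negative")
  }
  md
}

#' @rdname read_metadata
#' @param metadata Metadata tibble to write.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}
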