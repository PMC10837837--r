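# Shipped reference tables. Each lives in inst/extdata as a commented CSV with
# a version line; loaded once per session and cached.

read_shipped <- function(file) {
  path <- system.file("extdata", file, package = "ecosig", mustWork = TRUE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

shipped_table <- function(name, file) {
  key <- paste0("tbl_", name)
  if (is.null(the[[key]])) the[[key]] <- read_shipped(file)
  the[[key]]
}

#' Shipped reference tables
#'
#' Accessors for the data tables the package ships: the Kyte-Doolittle
#' hydropathy scale, the EMBOSS-style pKa set used by
#' [isoelectric_point()], the van der Waals radii used by [compute_sasa()],
#' and the background amino-acid composition used by the synthetic proteome
#' generator.
#'
#' @return A tibble; columns depend on the table (see the CSV headers under
#'   `inst/extdata`).
#' @export
#' @examples
#' hydropathy_scale()
hydropathy_scale <- function() shipped_table("kd", "kyte_doolittle.csv")

#' @rdname hydropathy_scale
#' @export
pka_set <- function() shipped_table("pka", "pka_emboss.csv")

#' @rdname hydropathy_scale
#' @export
vdw_radii <- function() shipped_table("vdw", "vdw_radii.csv")

#' @rdname hydropathy_scale
#' @export
aa_background <- function() shipped_table("aabg", "aa_background.csv")

# 20 standard amino acids, one-letter, fixed order used by all frequency vectors
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA_ONE <- setNames(names(AA_THREE), AA_THREE)

aa_background_vec <- function() {
  tb <- aa_background()
  v <- setNames(tb$freq, tb$aa)[AA_ORDER]
  v / sum(v)
}
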