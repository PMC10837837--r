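# Seeded genome generator: multi-clade genome sets with controlled GC and
# feature composition, planted regulatory signatures, and machine-readable
# truth. Sequence composition is variance-controlled: planted compositions
# are realised by exact-count shuffles (largest-remainder rounding), so
# recovery tests have tight, closed-form expectations.

largest_remainder <- function(n, probs) {
  probs <- probs / sum(probs)
  base <- floor(n * probs)
  rem <- n * probs - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  base
}

# randomised systematic rounding: integer counts summing to n, each within 1
# of n*p and with expectation exactly n*p (deterministic rounding would bias
# every short feature identically, shifting pooled compositions off target)
rand_round_counts <- function(n, probs) {
  probs <- probs / sum(probs)
  cum <- cumsum(probs) * n
  u <- runif(1)
  counts <- diff(c(0, floor(cum + u)))
  setNames(as.integer(counts), names(probs))
}

# random sequence with base counts at the target composition (randomised
# rounding, shuffled order)
seq_exact_comp <- function(n, probs, alphabet) {
  counts <- rand_round_counts(n, probs)
  paste(sample(rep(alphabet, counts)), collapse = "")
}

seq_exact_gc <- function(n, gc) {
  seq_exact_comp(n, c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2),
                 c("A", "C", "G", "T"))
}

# CDS: ATG + codons drawn from sense codons at a GC-tilted distribution + TAA
random_cds <- function(n_codons, gc) {
  codons <- all_codons()
  sense <- codons[Biostrings::GENETIC_CODE[codons] != "*"]
  pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(strsplit(sense, ""), function(ch) prod(pbase[ch]), numeric(1))
  body <- sample(sense, max(0, n_codons - 2), replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Configuration of the synthetic genome generator
#'
#' The defaults are the study conditions the generator emulates: four
#' subclades (nonsaline mesophilic Ia, nonsaline psychrophilic Ib, saline
#' mesophilic IIa, saline thermophilic IIb) with planted regulatory
#' signatures — tmRNA GC depressed in all three extremophilic clades,
#' promoter AT and sRNA counts raised in the psychrophile, insertion
#' sequences and operon density raised in the extremophiles — and habitat
#' metadata centred on MAT -1.6/8.9/12.1/45.5 degrees C and salinity below
#' 1% (clade I) versus above 5% NaCl m/v (clade II). Genome sizes are
#' desk-scale (100 kb) so composition statistics concentrate tightly.
#'
#' @param n_isolates Isolates per clade.
#' @param genome_length Total genome length (bp) per isolate.
#' @param n_contigs Contigs per genome.
#' @param clades Per-clade parameter tibble (see the function body for the
#'   default columns).
#' @param n_cds,cds_codon_range Number of CDS and codon-count range per CDS.
#' @param n_rrna,rrna_len,tmrna_len,n_promoters,promoter_len,srna_len,is_len,crispr_len
#'   Feature counts and lengths (bp).
#' @param mat_sd,salinity_sd Per-isolate jitter (centred, so clade means stay
#'   exactly at the planted values).
#' @return A config list for [make_clade_genomes()].
#' @export
genome_sim_config <- function(
    n_isolates = 6, genome_length = 100000, n_contigs = 2,
    clades = tibble::tibble(
      clade = c("Ia", "Ib", "IIa", "IIb"),
      gc = c(0.470, 0.473, 0.520, 0.480),
      tmrna_gc_offset = c(0, -0.05, -0.05, -0.05),
      rrna_gc_offset = c(0.06, 0.06, 0.08, 0.08),
      promoter_at = c(0.62, 0.68, 0.62, 0.62),
      mean_srna = c(30, 45, 30, 30),
      mean_is = c(10, 18, 18, 18),
      mean_operon = c(16, 24, 24, 24),
      mean_crispr = c(0.3, 0.5, 1.0, 1.6),
      mat = c(8.9, -1.6, 12.1, 45.5),
      salinity = c(0.5, 0.5, 6.0, 8.0)
    ),
    n_cds = 80, cds_codon_range = c(100, 300),
    n_rrna = 3, rrna_len = 1500, tmrna_len = 350,
    n_promoters = 30, promoter_len = 60,
    srna_len = 100, is_len = 800, crispr_len = 500,
    mat_sd = 1.5, salinity_sd = 0.2) {
  as.list(environment())
}

# pack feature sequences into contigs with random background gaps
pack_contig <- function(contig_len, feats, gc) {
  total_feat <- sum(nchar(feats$sequence))
  if (total_feat > contig_len) abort("infeasible packing: features exceed contig length")
  n <- nrow(feats)
  budget <- contig_len - total_feat
  cuts <- sort(runif(n))
  gaps <- diff(c(0, cuts, 1))
  gap_len <- largest_remainder(budget, gaps)
  pieces <- character(2 * n + 1)
  pos <- 0L
  starts <- integer(n)
  for (i in seq_len(n)) {
    pieces[2 * i - 1] <- seq_exact_gc(gap_len[i], gc)
    pos <- pos + gap_len[i]
    starts[i] <- pos + 1L
    s <- feats$sequence[i]
    if (feats$strand[i] == "-") s <- reverse_complement(s)
    pieces[2 * i] <- s
    pos <- pos + nchar(s)
  }
  pieces[2 * n + 1] <- seq_exact_gc(gap_len[n + 1], gc)
  list(sequence = paste(pieces, collapse = ""), starts = starts)
}

#' Generate a synthetic multi-clade genome set
#'
#' Produces genomes, annotations, metadata and truth for the clades of
#' `config`. Nucleotide composition is variance-controlled at the planted
#' targets; CDS are placed non-overlapping with valid start/stop codons;
#' tmRNA/rRNA/promoter sequences carry their planted composition offsets;
#' sRNA/insertion-sequence/CRISPR counts are Poisson at the planted means;
#' operon features span runs of consecutive CDS. Pure function of
#' `(config, seed)`.
#'
#' @param config From [genome_sim_config()].
#' @param seed Integer seed.
#' @return List with `genomes` (named list of genome tibbles), `annotations`
#'   (named list of annotation tibbles), `metadata` (tibble), `truth` (list).
#' @export
make_clade_genomes <- function(config = genome_sim_config(), seed = 1) {
  withr::with_seed(seed, make_clade_genomes_impl(config))
}

make_clade_genomes_impl <- function(cf) {
  genomes <- list()
  annotations <- list()
  meta_rows <- list()
  truth <- list(clades = cf$clades, isolates = list())

  for (ci in seq_len(nrow(cf$clades))) {
    cl <- cf$clades[ci, ]
    jit_mat <- rnorm(cf$n_isolates); jit_mat <- jit_mat - mean(jit_mat)
    jit_sal <- rnorm(cf$n_isolates); jit_sal <- jit_sal - mean(jit_sal)
    for (ii in seq_len(cf$n_isolates)) {
      iso <- sprintf("%s_%02d", cl$clade, ii)
      n_srna <- rpois(1, cl$mean_srna)
      n_is <- rpois(1, cl$mean_is)
      n_crispr <- rpois(1, cl$mean_crispr)
      n_operon <- rpois(1, cl$mean_operon)

      feats <- dplyr::bind_rows(
        tibble::tibble(feature_type = "tmRNA",
                       sequence = seq_exact_gc(cf$tmrna_len, cl$gc + cl$tmrna_gc_offset)),
        tibble::tibble(feature_type = "rRNA",
                       sequence = replicate(cf$n_rrna,
                                            seq_exact_gc(cf$rrna_len, cl$gc + cl$rrna_gc_offset))),
        tibble::tibble(feature_type = "promoter",
                       sequence = replicate(cf$n_promoters,
                                            seq_exact_gc(cf$promoter_len, 1 - cl$promoter_at))),
        tibble::tibble(feature_type = "sRNA",
                       sequence = if (n_srna) replicate(n_srna, seq_exact_gc(cf$srna_len, cl$gc)) else character()),
        tibble::tibble(feature_type = "insertion_sequence",
                       sequence = if (n_is) replicate(n_is, seq_exact_gc(cf$is_len, cl$gc)) else character()),
        tibble::tibble(feature_type = "CRISPR",
                       sequence = if (n_crispr) replicate(n_crispr, seq_exact_gc(cf$crispr_len, cl$gc)) else character()),
        tibble::tibble(feature_type = "CDS",
                       sequence = replicate(cf$n_cds, random_cds(
                         sample(cf$cds_codon_range[1]:cf$cds_codon_range[2], 1), cl$gc)))
      )
      feats$strand <- sample(c("+", "-"), nrow(feats), replace = TRUE)
      feats <- feats[sample(nrow(feats)), , drop = FALSE]

      if (sum(nchar(feats$sequence)) > cf$genome_length) {
        abort("infeasible packing: planted features exceed genome length")
      }
      # split features over contigs proportionally to contig length
      contig_len <- largest_remainder(cf$genome_length,
                                      rep(1 / cf$n_contigs, cf$n_contigs))
      contig_of <- sort(rep_len(seq_len(cf$n_contigs), nrow(feats)))
      ann <- list(); contigs <- character(cf$n_contigs)
      for (k in seq_len(cf$n_contigs)) {
        fk <- feats[contig_of == k, , drop = FALSE]
        packed <- pack_contig(contig_len[k], fk, cl$gc)
        contigs[k] <- packed$sequence
        ann[[k]] <- tibble::tibble(
          feature_type = fk$feature_type,
          contig_id = sprintf("%s_c%d", iso, k),
          start = packed$starts,
          end = packed$starts + nchar(fk$sequence) - 1L,
          strand = fk$strand)
      }
      ann <- dplyr::bind_rows(ann)

      # operons: spans of 2-3 consecutive CDS on the same contig
      cds_ann <- ann[ann$feature_type == "CDS", , drop = FALSE]
      op_rows <- NULL
      if (n_operon > 0 && nrow(cds_ann) >= 2) {
        cds_ann <- dplyr::arrange(cds_ann, .data$contig_id, .data$start)
        starts_ok <- which(cds_ann$contig_id[-nrow(cds_ann)] ==
                             cds_ann$contig_id[-1])
        n_op <- min(n_operon, length(starts_ok))
        pick <- sort(starts_ok[sample.int(length(starts_ok), n_op)])
        op_rows <- tibble::tibble(
          feature_type = "operon",
          contig_id = cds_ann$contig_id[pick],
          start = cds_ann$start[pick],
          end = cds_ann$end[pick + 1],
          strand = cds_ann$strand[pick])
        ann <- dplyr::bind_rows(ann, op_rows)
      }
      ann$attributes <- rep(list(character()), nrow(ann))
      ann <- dplyr::arrange(ann, .data$contig_id, .data$start)

      genomes[[iso]] <- tibble::tibble(
        contig_id = sprintf("%s_c%d", iso, seq_len(cf$n_contigs)),
        sequence = contigs)
      annotations[[iso]] <- ann
      meta_rows[[iso]] <- tibble::tibble(
        isolate_id = iso, clade_label = cl$clade, habitat = "synthetic",
        MAT = cl$mat + cf$mat_sd * jit_mat[ii],
        salinity = max(0, cl$salinity + cf$salinity_sd * jit_sal[ii]),
        completeness = round(runif(1, 97, 100), 2),
        contamination = round(runif(1, 0, 1), 2),
        n_contigs = cf$n_contigs, is_type_strain = FALSE)
      truth$isolates[[iso]] <- list(
        clade = cl$clade, gc = cl$gc,
        tmrna_gc = cl$gc + cl$tmrna_gc_offset,
        rrna_gc = cl$gc + cl$rrna_gc_offset,
        promoter_at = cl$promoter_at,
        n_srna = n_srna, n_is = n_is, n_crispr = n_crispr,
        n_operon = if (is.data.frame(op_rows)) nrow(op_rows) else 0L,
        n_cds = cf$n_cds)
    }
  }
  list(genomes = genomes, annotations = annotations,
       metadata = dplyr::bind_rows(meta_rows), truth = truth)
}
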