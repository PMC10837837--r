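# Proteome composition indices: amino-acid frequencies, GRAVY, isoelectric
# point, composition ratios, percentage-difference signatures and the
# two-sample KS contrast.

aa_counts <- function(sequences) {
  s <- Biostrings::AAStringSet(toupper(sequences))
  f <- Biostrings::alphabetFrequency(s)
  counts <- colSums(f)[AA_ORDER]
  skipped <- sum(colSums(f)) - sum(counts)
  list(counts = counts, skipped = skipped)
}

#' Amino-acid frequencies of a protein set
#'
#' Frequencies of the 20 standard amino acids pooled over all sequences.
#' Non-standard letters (X, B, Z, U, ...) are skipped; the skip count is
#' reported via a message when non-zero.
#'
#' @param sequences Character vector of protein sequences.
#' @return Named 20-long numeric vector summing to 1 (order fixed as
#'   `A R N D C Q E G H I L K M F P S T W Y V`); all-`NA` if no residue is
#'   countable.
#' @export
#' @examples
#' aa_frequencies(c("AR", "AR"))
aa_frequencies <- function(sequences) {
  ac <- aa_counts(sequences)
  if (ac$skipped > 0) inform(paste0(ac$skipped, " non-standard residue(s) skipped"))
  if (sum(ac$counts) == 0) {
    warn("zero countable residues; frequencies undefined")
    return(setNames(rep(NA_real_, 20), AA_ORDER))
  }
  ac$counts / sum(ac$counts)
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the counted residues of each sequence.
#' Non-standard letters are skipped.
#'
#' @param sequence Character vector of protein sequences (one score each).
#' @param scale Hydropathy scale as a tibble (`aa`, `hydropathy`); defaults to
#'   the shipped Kyte-Doolittle table.
#' @return Numeric vector of GRAVY scores; `NA` where no residue is countable.
#' @export
#' @examples
#' gravy("AR")
gravy <- function(sequence, scale = hydropathy_scale()) {
  lut <- setNames(scale$hydropathy, scale$aa)
  vapply(strsplit(toupper(sequence), ""), function(ch) {
    h <- lut[ch]
    h <- h[!is.na(h)]
    if (length(h) == 0) NA_real_ else mean(h)
  }, numeric(1))
}

net_charge <- function(counts_pos, counts_neg, pka_pos, pka_neg, ph) {
  pos <- sum(counts_pos / (1 + 10^(ph - pka_pos)))
  neg <- sum(counts_neg / (1 + 10^(pka_neg - ph)))
  pos - neg
}

#' Isoelectric point of a protein
#'
#' Bisection root of the Henderson-Hasselbalch net charge
#' `Q(pH) = sum of positive terms (N-terminus, Lys, Arg, His) - sum of
#' negative terms (C-terminus, Asp, Glu, Cys, Tyr)` over the search interval
#' pH 0..14, to `|Q| < tol`. The pKa set is a named, versioned table
#' (EMBOSS-style default, see [pka_set()]).
#'
#' @param sequence Character vector of protein sequences.
#' @param pka pKa table (`group`, `pka`, `charge`).
#' @param tol Charge tolerance at the returned pH.
#' @return Numeric vector of pI values.
#' @export
#' @examples
#' isoelectric_point("KKKKKK")
isoelectric_point <- function(sequence, pka = pka_set(), tol = 1e-4) {
  pk <- setNames(pka$pka, pka$group)
  chg <- setNames(pka$charge, pka$group)
  vapply(toupper(sequence), function(s) {
    ch <- strsplit(s, "")[[1]]
    groups <- c("Nterm", "Cterm", intersect(names(pk), c("K", "R", "H", "D", "E", "C", "Y")))
    n <- c(Nterm = 1, Cterm = 1, table(factor(ch, levels = setdiff(groups, c("Nterm", "Cterm")))))
    pos <- groups[chg[groups] == "positive"]
    neg <- groups[chg[groups] == "negative"]
    q <- function(ph) net_charge(n[pos], n[neg], pk[pos], pk[neg], ph)
    lo <- 0; hi <- 14
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      qm <- q(mid)
      if (abs(qm) < tol) return(mid)
      if (qm > 0) lo <- mid else hi <- mid
    }
    abort("isoelectric point bisection did not converge")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Amino-acid composition ratio
#'
#' Ratio of summed frequencies of a numerator set to a denominator set, e.g.
#' Lys/Arg or Glu/Asp.
#'
#' @param f Named amino-acid frequency vector (one-letter names).
#' @param numerator,denominator Character vectors of one-letter codes.
#' @return The ratio, or `NA` with a warning for a zero denominator.
#' @export
#' @examples
#' aa_ratio(c(K = 0.06, R = 0.05), "K", "R")
aa_ratio <- function(f, numerator, denominator) {
  num <- sum(f[numerator])
  den <- sum(f[denominator])
  if (is.na(den) || den == 0) {
    warn("zero denominator frequency; ratio undefined")
    return(NA_real_)
  }
  unname(num / den)
}

#' Percentage-difference composition signature
#'
#' Per-amino-acid percentage difference of a target frequency vector relative
#' to a reference: `d = 100 * (f_target - f_reference) / f_reference`.
#' Amino acids with zero reference frequency get `NA`.
#'
#' @param f_target,f_reference Named frequency vectors over the same names.
#' @return Named numeric vector of percentage differences.
#' @export
#' @examples
#' composition_signature(c(D = 0.055), c(D = 0.050))
composition_signature <- function(f_target, f_reference) {
  stopifnot(length(f_target) == length(f_reference))
  if (!is.null(names(f_reference))) f_target <- f_target[names(f_reference)]
  d <- 100 * (f_target - f_reference) / f_reference
  d[!is.na(f_reference) & f_reference == 0] <- NA_real_
  d
}

#' Two-sample Kolmogorov-Smirnov contrast
#'
#' Two-sided two-sample KS test. With at least 50 observations per side the
#' asymptotic p-value is used; below that, the exact p-value when the data
#' are tie-free and otherwise a seeded permutation p-value (the permutation
#' draws use the current RNG state, so wrap in [withr::with_seed()] or set a
#' seed for reproducibility).
#'
#' @param x,y Numeric vectors, each of length >= 5.
#' @param n_perm Number of permutations for the tied small-sample case.
#' @return Tibble with `statistic` (D), `p_value`, `method`.
#' @export
ks_contrast <- function(x, y, n_perm = 10000) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 5 || length(y) < 5) abort("each sample needs n >= 5")
  ties <- anyDuplicated(c(x, y)) > 0
  big <- min(length(x), length(y)) >= 50
  if (big) {
    ht <- suppressWarnings(ks.test(x, y, exact = FALSE))
    return(tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                          method = "asymptotic"))
  }
  if (!ties) {
    ht <- suppressWarnings(ks.test(x, y, exact = TRUE))
    return(tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                          method = "exact"))
  }
  d_obs <- unname(suppressWarnings(ks.test(x, y))$statistic)
  pooled <- c(x, y)
  nx <- length(x)
  d_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), nx)
    unname(suppressWarnings(ks.test(pooled[idx], pooled[-idx]))$statistic)
  }, numeric(1))
  tibble::tibble(statistic = d_obs,
                 p_value = (1 + sum(d_perm >= d_obs - 1e-12)) / (1 + n_perm),
                 method = "permutation")
}

#' Proteome composition vector of one isolate
#'
#' Pools all proteins of an isolate into amino-acid frequencies and computes
#' the per-isolate mean GRAVY and isoelectric point plus standard composition
#' ratios (Lys/Arg, Glu/Asp, Asn/Gln).
#'
#' @param proteins Tibble with columns `protein_id`, `sequence`.
#' @param isolate_id Isolate identifier carried into the output.
#' @return One-row tibble; the frequency vector as a list column `f`.
#' @export
proteome_composition <- function(proteins, isolate_id = "isolate") {
  freq <- suppressMessages(aa_frequencies(proteins$sequence))
  ratios <- suppressWarnings(c(
    lys_arg = aa_ratio(freq, "K", "R"),
    glu_asp = aa_ratio(freq, "E", "D"),
    asn_gln = aa_ratio(freq, "N", "Q")))
  tibble::tibble(
    isolate_id = isolate_id,
    f = list(freq),
    GRAVY = mean(gravy(proteins$sequence), na.rm = TRUE),
    pI = mean(isoelectric_point(proteins$sequence), na.rm = TRUE),
    lys_arg = ratios[["lys_arg"]],
    glu_asp = ratios[["glu_asp"]],
    asn_gln = ratios[["asn_gln"]]
  )
}
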