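# Genome-scale features: GC arithmetic, codon statistics, N50, the QC gate,
# AAI deduplication, clade summaries and the rank-sum contrast.

test_that("gc_content counts unambiguous bases only", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATGCNN"), 0.5)
  expect_equal(gc_content("atgc"), 0.5)
  expect_warning(v <- gc_content("NNN"), "undefined")
  expect_true(is.na(v))
})

test_that("gc and at contents are complementary and strand-invariant", {
  withr::local_seed(4)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    expect_equal(gc_content(s) + at_content(s), 1)
    expect_equal(gc_content(reverse_complement(s)), gc_content(s))
  }
})

test_that("positional GC pools codon positions over all CDS", {
  expect_equal(unname(positional_gc("GGGGGG")), c(1, 1, 1))
  expect_equal(unname(positional_gc("ATGGCATAA")), c(1/3, 1/3, 1/3))
  expect_warning(pg <- positional_gc("ATGGCATAAG"), "partial codon")
  expect_equal(unname(pg), c(1/3, 1/3, 1/3))  # trailing G dropped
})

test_that("codon usage frequencies and RSCU match hand enumeration", {
  cu <- codon_usage("ATGTGG")
  expect_equal(sum(cu), 1)
  expect_equal(unname(cu["ATG"]), 0.5)
  expect_equal(unname(cu["TGG"]), 0.5)

  # equal use of a 4-codon family (Gly) has RSCU 1 for each member
  r <- codon_usage("GGTGGCGGAGGG", mode = "RSCU")
  expect_equal(unname(r[c("GGT", "GGC", "GGA", "GGG")]), rep(1, 4))

  # Phe family TTT TTT TTC: counts 2,1 against family mean 1.5
  r2 <- codon_usage(c("TTTTTTTTC"), mode = "RSCU")
  expect_equal(unname(r2["TTT"]), 4/3)
  expect_equal(unname(r2["TTC"]), 2/3)

  # single-codon family present has RSCU 1
  expect_equal(unname(codon_usage("ATG", mode = "RSCU")["ATG"]), 1)
})

test_that("n50 matches its definition, brute force, and is order-invariant", {
  expect_equal(n50(100), 100)
  expect_equal(n50(c(100, 200, 300, 400)), 300)
  expect_equal(n50(c(400, 100, 300, 200)), 300)
  expect_error(n50(numeric(0)), "empty")
  withr::local_seed(5)
  for (i in 1:200) {
    lens <- sample.int(5000, sample(1:30, 1), replace = TRUE)
    expect_identical(n50(lens), oracle_n50(lens))
  }
})

test_that("qc gate fails on any violated criterion with reasons", {
  metrics <- tibble::tibble(
    isolate_id = c("ok", "many_contigs", "short_n50", "incomplete",
                   "contaminated", "missing"),
    n_contigs = c(120, 301, 120, 120, 120, NA),
    N50 = c(50000, 50000, 19999, 50000, 50000, 50000),
    completeness = c(98, 98, 98, 94.9, 98, 98),
    contamination = c(1, 1, 1, 1, 5.1, 1))
  out <- qc_filter(metrics)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reasons[[2]], "contigs>300")
  expect_equal(out$reasons[[3]], "N50<20000")
  expect_equal(out$reasons[[6]], "missing metric")
})

test_that("qc gate is monotone in its thresholds", {
  withr::local_seed(6)
  metrics <- tibble::tibble(
    isolate_id = paste0("g", 1:50),
    n_contigs = sample(50:400, 50, TRUE),
    N50 = sample(5000:60000, 50, TRUE),
    completeness = runif(50, 90, 100),
    contamination = runif(50, 0, 8))
  strict <- qc_filter(metrics)
  relaxed <- qc_filter(metrics, max_contigs = 350, min_n50 = 15000,
                       min_completeness = 92, max_contamination = 6)
  expect_true(all(relaxed$pass[strict$pass]))
})

test_that("AAI dedup keeps one representative per component", {
  ids <- c("a", "b", "c")
  m <- matrix(98, 3, 3, dimnames = list(ids, ids)); diag(m) <- 100
  expect_equal(dedup_aai(m), c("a", "b", "c"))

  # pair above threshold: higher completeness wins
  m2 <- m; m2["a", "b"] <- m2["b", "a"] <- 99.6
  md <- tibble::tibble(isolate_id = ids, completeness = c(96, 99, 98),
                       contamination = c(1, 1, 1))
  expect_equal(dedup_aai(m2, md), c("b", "c"))

  # chain a-b, b-c is one component even though a-c is below threshold
  m3 <- m
  m3["a", "b"] <- m3["b", "a"] <- 99.6
  m3["b", "c"] <- m3["c", "b"] <- 99.6
  m3["a", "c"] <- m3["c", "a"] <- 99.0
  expect_equal(length(dedup_aai(m3, md)), 1)

  m4 <- m; m4["a", "b"] <- 99.6  # asymmetric
  expect_error(dedup_aai(m4), "asymmetric")
})

test_that("AAI dedup is idempotent and leaves no near-duplicate pair", {
  withr::local_seed(7)
  for (rep in 1:10) {
    n <- 12
    ids <- sprintf("i%02d", 1:n)
    m <- matrix(runif(n * n, 90, 99.4), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2; diag(m) <- 100
    # plant a duplicated block
    blk <- sample(n, 3)
    m[blk, blk] <- 99.8; diag(m) <- 100
    kept <- dedup_aai(m)
    sub <- m[kept, kept, drop = FALSE]; diag(sub) <- 0
    expect_true(all(sub < 99.5))
    expect_equal(dedup_aai(sub + diag(100, length(kept))), kept)
  }
})

test_that("coding density is CDS per kb", {
  expect_equal(coding_density(3000, 3e6), 1)
  expect_equal(coding_density(900, 1e6), 0.9)
  expect_equal(coding_density(0, 1e6), 0)
})

test_that("clade summaries use sample sd and report n per cell", {
  ft <- tibble::tibble(isolate_id = c("a", "b", "c", "d"),
                       x = c(2, 4, 5, 5), y = c(1, NA, 2, 2))
  clades <- tibble::tibble(isolate_id = c("a", "b", "c", "d", "e"),
                           clade = c("A", "A", "B", "B", "C"))
  expect_warning(s <- clade_summary(ft, clades), "omitted")
  a_x <- s[s$clade == "A" & s$feature == "x", ]
  expect_equal(a_x$mean, 3)
  expect_equal(a_x$sd, sqrt(2))
  a_y <- s[s$clade == "A" & s$feature == "y", ]
  expect_equal(a_y$n, 1)
  expect_true(is.na(a_y$sd))
  b_x <- s[s$clade == "B" & s$feature == "x", ]
  expect_equal(b_x$sd, 0)
})

test_that("rank contrast gives exact small-sample p-values and stars", {
  r <- rank_contrast(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1)  # smallest attainable two-sided p at 3 vs 3
  expect_equal(r$star, "ns")
  same <- rank_contrast(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(same$p_value, 0.9)
  expect_error(rank_contrast(1, c(1, 2)), "n >= 2")
  expect_equal(star_class(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
})

test_that("genome feature vector assembles the per-isolate statistics", {
  genome <- tibble::tibble(contig_id = "c1", sequence = strrep("ACGT", 300))
  ann <- tibble::tibble(
    feature_type = c("CDS", "CRISPR"), contig_id = "c1",
    start = c(1L, 100L), end = c(9L, 150L), strand = "+",
    attributes = list(character(), character()))
  gf <- genome_features(genome, ann, "iso1")
  expect_equal(gf$genome_size_bp, 1200)
  expect_equal(gf$n_CDS, 1)
  expect_equal(gf$n_CRISPR, 1)
  expect_equal(gf$GC, 0.5)
  expect_equal(gf$coding_density, 1 / 1.2)
  expect_equal(sum(gf$codon_frequency[[1]]), 1)
})
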