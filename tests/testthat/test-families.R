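# Protein-family clustering and conservation statistics.

test_that("alignment identity and coverage match hand-checked cases", {
  a <- align_identity("AAAA", "AAAA")
  expect_equal(a$identity, 1)
  expect_equal(a$coverage, 1)
  b <- align_identity("AAAA", "AAAT")
  expect_equal(b$identity, 0.75)
})

test_that("clustering joins near-identical sequences and separates random ones", {
  withr::local_seed(13)
  # identical pair -> one family
  pr <- tibble::tibble(protein_id = c("p1", "p2"),
                       sequence = rep(random_protein(80), 2))
  expect_equal(length(unique(cluster_families(pr)$family_id)), 1)

  # two random length-100 sequences: expected identity ~5%, far below 0.5
  pr2 <- tibble::tibble(protein_id = c("q1", "q2"),
                        sequence = c(random_protein(100), random_protein(100)))
  expect_equal(length(unique(cluster_families(pr2)$family_id)), 2)

  # a 60%-identical full-length mutant joins its parent
  parent <- random_protein(100)
  ch <- strsplit(parent, "")[[1]]
  mut_at <- sample(100, 40)
  for (k in mut_at) ch[k] <- sample(setdiff(LETTERS[LETTERS %in% c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")], ch[k]), 1)
  mutant <- paste(ch, collapse = "")
  expect_gte(align_identity(parent, mutant)$identity, 0.55)
  pr3 <- tibble::tibble(protein_id = c("r1", "r2"),
                        sequence = c(parent, mutant))
  expect_equal(length(unique(cluster_families(pr3)$family_id)), 1)
})

test_that("clustering is deterministic under input permutation", {
  withr::local_seed(14)
  base <- replicate(4, random_protein(60))
  prots <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:8),
    sequence = c(base, vapply(base, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[sample(60, 6)] <- "A"
      paste(ch, collapse = "")
    }, character(1))))
  ref <- cluster_families(prots)
  perm <- cluster_families(prots[sample(nrow(prots)), ])
  ref_sets <- sort(vapply(split(ref$protein_id, ref$family_id),
                          function(x) paste(sort(x), collapse = ","), character(1)))
  perm_sets <- sort(vapply(split(perm$protein_id, perm$family_id),
                           function(x) paste(sort(x), collapse = ","), character(1)))
  expect_identical(unname(ref_sets), unname(perm_sets))
})

test_that("family filtering uses half the genome count by default", {
  fams <- tibble::tibble(
    protein_id = sprintf("p%03d", 1:77),
    family_id = rep(c("F1", "F2"), c(39, 38)))
  kept <- filter_families(fams, n_genomes = 78)
  expect_equal(unique(kept$family_id), "F1")  # 39 >= ceiling(78/2), 38 below
  expect_equal(nrow(filter_families(fams[0, ], n_genomes = 78)), 0)
  expect_error(filter_families(fams), "n_genomes or min_members")
})

test_that("mean pairwise identity matches construction", {
  fam <- tibble::tibble(protein_id = c("a", "b", "c"),
                        family_id = "F1",
                        sequence = rep("GATTACAKLM", 3))
  mpi <- mean_pairwise_identity(fam)
  expect_equal(mpi$mean_identity, 100)
  expect_equal(mpi$sd_identity, 0)

  pair <- tibble::tibble(protein_id = c("a", "b"), family_id = "F1",
                         sequence = c("AAAA", "AAAT"))
  expect_equal(mean_pairwise_identity(pair)$mean_identity, 75)

  single <- tibble::tibble(protein_id = "a", family_id = "F1", sequence = "AAA")
  expect_true(is.na(mean_pairwise_identity(single)$mean_identity))
})

test_that("planted within-family identity is recovered within 2 points", {
  cfg <- protein_sim_config(n_families = 2, members_per_clade = 2,
                            identity_sd = 0)
  sim <- make_protein_families(cfg, seed = 21)
  fams <- dplyr::rename(sim$proteins, family_id = family_id)
  mpi <- mean_pairwise_identity(fams[fams$family_id == "F001", ])
  expect_lt(abs(mpi$mean_identity - 80), 2)
})
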